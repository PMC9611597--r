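# Independent oracles and small fixture builders used across the suite.

# Adjusted Rand index by direct pair counting (independent of any package).
helper_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / (0.5 * (sum_a + sum_b) - expected)
}

# Deterministic 2-D quadrature over the flat-prior posterior of the
# intercept-only three-category multinomial logit: returns E[beta_1], E[beta_2].
quadrature_posterior_means <- function(y, lim = 6, step = 0.01) {
  n <- length(y)
  n1 <- sum(y == 1)
  n2 <- sum(y == 2)
  gr <- seq(-lim, lim, by = step)
  ones <- rep(1, length(gr))
  lp <- outer(gr * n1, gr * n2, "+") -
    n * log(1 + exp(gr) %o% ones + ones %o% exp(gr))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  c(sum(rowSums(w) * gr), sum(colSums(w) * gr))
}

# Brute-force multinomial log-likelihood by direct substitution into the
# logit-link probabilities (no log-sum-exp tricks).
brute_force_loglik <- function(y, eta1, eta2) {
  ll <- 0
  for (i in seq_along(y)) {
    denom <- 1 + exp(eta1[i]) + exp(eta2[i])
    p <- c(exp(eta1[i]) / denom, exp(eta2[i]) / denom, 1 / denom)
    ll <- ll + log(p[y[i]])
  }
  ll
}

# Planted-template data: n respondents split over the first three category
# templates with flip noise.
planted_data <- function(n_per_cat = 100, epsilon = 0.05) {
  labels <- rep(1:3, each = n_per_cat)
  data <- starmnl:::emit_bulk(labels, validate_responses(default_templates()),
                              epsilon)
  list(data = data, labels = labels)
}

# Small standard survey simulation reused by several files.
small_sim <- function(seed = 7, rows = 4, cols = 4, psus = 4,
                      resp = c(15, 25), ...) {
  g <- build_region_lattice(rows, cols)
  sim <- simulate_survey(g, psus_per_region = psus,
                         respondents_per_psu = resp, seed = seed, ...)
  sim$graph <- g
  sim
}
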