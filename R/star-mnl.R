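#' Bayesian multinomial-logit structured additive regression
#'
#' Fits a three-category multinomial logit model in which the linear
#' predictor of each non-reference category k = 1, 2 (category 3 is the
#' reference, \eqn{\eta_{i3} = 0}) is
#' \deqn{\eta_{ik} = x_i' \beta_k + f_k(a_i) + b_{u(i),k} + s_{j(i),k}}
#' with flat priors on the fixed effects \eqn{\beta_k}, a degree-3 P-spline
#' \eqn{f_k} with second-order random-walk prior on its coefficients, iid
#' Gaussian PSU effects \eqn{b}, and an intrinsic Markov-random-field prior
#' on the region effects \eqn{s} (conditional mean = neighbour average,
#' conditional variance \eqn{\tau^2_s / N_j}).  All three variances carry
#' IG(0.001, 0.001) hyperpriors; priors are independent across k.
#' Estimation is by Gibbs sampling with Polya-Gamma augmentation, which
#' yields closed-form Gaussian and inverse-gamma full conditionals.
#'
#' The model terms are declared in the formula: parametric covariates
#' appear as usual, \code{s(age)} requests the age smooth, \code{re(psu)}
#' the unstructured PSU effect and \code{mrf(region)} the spatially
#' structured region effect (which requires \code{graph}).  Dropping
#' \code{mrf()} gives the non-spatial null model; the two code paths are
#' otherwise identical.
#'
#' After every sweep the region effects are re-centred to sum to zero and
#' the fitted smooth is mean-centred, with both levels absorbed into the
#' intercept, fixing the levels the improper priors leave free.
#'
#' @param formula e.g. \code{category ~ urban + educ + income + s(age) +
#'   re(psu) + mrf(region)}.  The response must hold integer category
#'   labels; rows outside categories 1-3 are dropped.
#' @param data respondent table.
#' @param graph \code{\link{region_graph}} (required with an \code{mrf}
#'   term); must be connected with no islands.
#' @param iterations,burnin,thin MCMC settings; retained draws per chain =
#'   \code{(iterations - burnin) / thin}.
#' @param chains number of chains; chain c uses seed \code{seed + c - 1}.
#' @param seed integer seed.
#' @param knots,degree P-spline settings (defaults 20 equidistant knot
#'   intervals, degree 3, hence M = 23 basis functions).
#' @param ig_a,ig_b inverse-gamma hyperparameters (default 0.001, 0.001).
#' @return Object of class \code{star_mnl} with elements \code{chains}
#'   (per-chain draws), \code{summary}, \code{dic}, \code{design},
#'   \code{model} ("full"/"null"), \code{settings}.
#' @seealso \code{\link{compute_dic}}, \code{\link{summarize_posterior}},
#'   \code{\link{region_effects}}, \code{\link{psu_effects}}
#' @export
star_mnl <- function(formula, data, graph = NULL,
                     iterations = 12000L, burnin = 2000L, thin = 10L,
                     chains = 1L, seed = 1L,
                     knots = 20L, degree = 3L,
                     ig_a = 0.001, ig_b = 0.001) {
  cl <- match.call()
  tf <- stats::terms(formula, specials = c("s", "re", "mrf"))
  labels <- as.integer(eval(attr(tf, "variables")[[2]], data,
                            environment(formula)))
  keep <- which(labels %in% 1:3)
  if (!length(keep)) stop("no respondents in categories 1-3")
  d2 <- data[keep, , drop = FALSE]
  y <- labels[keep]
  n <- length(y)

  tl <- attr(tf, "term.labels")
  t_s <- grep("^s\\(", tl, value = TRUE)
  t_re <- grep("^re\\(", tl, value = TRUE)
  t_mrf <- grep("^mrf\\(", tl, value = TRUE)
  if (length(t_s) > 1L || length(t_re) > 1L || length(t_mrf) > 1L)
    stop("at most one s(), re() and mrf() term is supported")
  param <- setdiff(tl, c(t_s, t_re, t_mrf))

  # canonical factor coding (references rural / none / poorest)
  if (!is.null(d2$educ))
    d2$educ <- factor(as.character(d2$educ), levels = educ_levels())
  if (!is.null(d2$income))
    d2$income <- factor(as.character(d2$income), levels = income_levels())

  X <- if (length(param))
    stats::model.matrix(stats::reformulate(param), d2)
  else matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (nrow(X) != n) stop("covariates contain missing values")

  inner_var <- function(term) sub("^[a-z]+\\(([^),]+).*$", "\\1", term)

  use_spline <- length(t_s) == 1L
  if (use_spline) {
    age <- d2[[inner_var(t_s)]]
    if (is.null(age)) stop("spline variable not found: ", inner_var(t_s))
    B <- bspline_basis(age, knots = knots, degree = degree)
    M <- ncol(B)
    nbc <- degree + 1L
    first_nz <- max.col(B != 0, ties.method = "first")
    bstart <- pmin(first_nz, M - nbc + 1L)
    Bw <- vapply(0:(nbc - 1L), function(a) B[cbind(seq_len(n), bstart + a)],
                 numeric(n))
    K <- rw2_penalty(M)
  } else {
    age <- NULL; B <- NULL; M <- 0L
    Bw <- matrix(0, n, 1L); bstart <- rep(1L, n); K <- matrix(0, 1L, 1L)
  }

  use_psu <- length(t_re) == 1L
  if (use_psu) {
    psu_raw <- d2[[inner_var(t_re)]]
    if (is.null(psu_raw)) stop("re() variable not found: ", inner_var(t_re))
    psu_ids <- sort(unique(psu_raw))
    psu_index <- match(psu_raw, psu_ids)
  } else {
    psu_ids <- NULL; psu_index <- rep(1L, n)
  }

  use_spatial <- length(t_mrf) == 1L
  if (use_spatial) {
    if (is.null(graph)) stop("mrf() term requires a region adjacency graph")
    if (any(graph$islands))
      stop("graph has island regions; the intrinsic MRF prior requires neighbours")
    if (max(graph_components(graph)) > 1L)
      stop("graph is disconnected; the intrinsic MRF prior requires a connected graph")
    region_raw <- as.character(d2[[inner_var(t_mrf)]])
    region_ids <- graph$region_ids
    if (any(!region_raw %in% region_ids))
      stop("region absent from graph: ", setdiff(region_raw, region_ids)[1])
    region_index <- match(region_raw, region_ids)
    nb0 <- lapply(graph$neighbors, function(x) as.integer(x - 1L))
  } else {
    region_ids <- NULL; region_index <- rep(1L, n); nb0 <- list(integer(0))
  }

  run <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    run[[ch]] <- .star_mcmc_cpp(
      X, Bw, as.integer(bstart - 1L), as.integer(M), K,
      as.integer(psu_index - 1L), as.integer(if (use_psu) length(psu_ids) else 1L),
      as.integer(region_index - 1L),
      as.integer(if (use_spatial) length(region_ids) else 1L),
      nb0, as.integer(y), use_spline, use_psu, use_spatial,
      as.integer(iterations), as.integer(burnin), as.integer(thin),
      ig_a, ig_b)
  }

  design <- list(X = X, B = B, age = age, y = y,
                 psu_index = if (use_psu) psu_index else NULL,
                 region_index = if (use_spatial) region_index else NULL,
                 psu_ids = psu_ids, region_ids = region_ids, keep = keep)

  fit <- structure(
    list(call = cl, formula = formula,
         model = if (use_spatial) "full" else "null",
         chains = run, design = design,
         has = list(spline = use_spline, psu = use_psu, spatial = use_spatial),
         settings = list(iterations = iterations, burnin = burnin,
                         thin = thin, chains = chains, seed = seed,
                         knots = knots, degree = degree,
                         ig_a = ig_a, ig_b = ig_b)),
    class = "star_mnl")
  fit$summary <- .star_summary(fit)
  fit$dic <- .star_dic(fit)
  fit
}

# pooled draws of one block as a (draws x params) matrix
pooled_draws <- function(fit, block) {
  mats <- lapply(fit$chains, function(ch) {
    a <- ch[[block]]
    if (length(a) == 0L) return(NULL)
    if (block == "tau2") return(t(a))
    # cube p x 2 x ndraws -> ndraws x (2p), category-major blocks
    d <- dim(a)
    t(matrix(a, d[1] * d[2], d[3]))
  })
  do.call(rbind, mats)
}

block_names <- function(fit, block) {
  switch(block,
         beta = as.vector(outer(colnames(fit$design$X), 1:2,
                                function(nm, k) paste0(nm, "_k", k))),
         gamma = as.vector(outer(seq_len(ncol(fit$design$B)), 1:2,
                                 function(m, k) sprintf("gamma%02d_k%d", m, k))),
         b = as.vector(outer(fit$design$psu_ids, 1:2,
                             function(u, k) paste0("psu", u, "_k", k))),
         s = as.vector(outer(fit$design$region_ids, 1:2,
                             function(j, k) paste0(j, "_k", k))),
         tau2 = c("tau2_age_k1", "tau2_age_k2", "tau2_psu_k1", "tau2_psu_k2",
                  "tau2_region_k1", "tau2_region_k2"))
}

#' Posterior summaries of MCMC draws
#'
#' Column-wise posterior median and central 95\% credible interval
#' (type-7 quantiles) of a draws-by-parameters matrix.
#'
#' @param draws numeric matrix, one column per parameter.
#' @param exp_transform also report \code{exp()} of the median and interval
#'   endpoints (relative odds ratios for logit coefficients); monotone, so
#'   the interval order is preserved.
#' @return data.frame with columns \code{parameter}, \code{median},
#'   \code{q2.5}, \code{q97.5} (and \code{or_*} columns when transformed).
#' @export
summarize_posterior <- function(draws, exp_transform = FALSE) {
  draws <- as.matrix(draws)
  if (!nrow(draws)) stop("no retained draws to summarise")
  qs <- t(apply(draws, 2L, stats::quantile,
                probs = c(0.5, 0.025, 0.975), type = 7, names = FALSE))
  out <- data.frame(parameter = colnames(draws) %||% paste0("par", seq_len(ncol(draws))),
                    median = qs[, 1], q2.5 = qs[, 2], q97.5 = qs[, 3],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (exp_transform) {
    out$or_median <- exp(out$median)
    out$or_q2.5 <- exp(out$q2.5)
    out$or_q97.5 <- exp(out$q97.5)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.star_summary <- function(fit) {
  beta <- pooled_draws(fit, "beta")
  colnames(beta) <- block_names(fit, "beta")
  out <- list(beta = summarize_posterior(beta, exp_transform = TRUE))
  if (fit$has$spline) {
    g <- pooled_draws(fit, "gamma"); colnames(g) <- block_names(fit, "gamma")
    out$gamma <- summarize_posterior(g)
  }
  for (blk in c("b", "s")) {
    if ((blk == "b" && fit$has$psu) || (blk == "s" && fit$has$spatial)) {
      d <- pooled_draws(fit, blk); colnames(d) <- block_names(fit, blk)
      out[[blk]] <- summarize_posterior(d)
    }
  }
  tau <- pooled_draws(fit, "tau2"); colnames(tau) <- block_names(fit, "tau2")
  keep_tau <- c(rep(fit$has$spline, 2), rep(fit$has$psu, 2), rep(fit$has$spatial, 2))
  out$tau2 <- if (any(keep_tau))
    summarize_posterior(tau[, keep_tau, drop = FALSE]) else NULL
  out
}

# posterior means of every parameter entering eta, then plug-in deviance
.star_dic <- function(fit) {
  dev <- unlist(lapply(fit$chains, `[[`, "deviance"))
  des <- fit$design
  cm <- function(block) {
    d <- pooled_draws(fit, block)
    if (is.null(d)) return(NULL)
    matrix(colMeans(d), ncol = 2L)
  }
  beta <- cm("beta")
  eta <- vapply(1:2, function(k) {
    e <- drop(des$X %*% beta[, k])
    if (fit$has$spline) e <- e + drop(des$B %*% cm("gamma")[, k])
    if (fit$has$psu) e <- e + cm("b")[des$psu_index, k]
    if (fit$has$spatial) e <- e + cm("s")[des$region_index, k]
    e
  }, numeric(length(des$y)))
  m <- pmax(0, eta[, 1], eta[, 2])
  lse <- m + log(exp(-m) + exp(eta[, 1] - m) + exp(eta[, 2] - m))
  etay <- ifelse(des$y == 3L, 0, eta[cbind(seq_along(des$y), pmin(des$y, 2L))])
  dhat <- -2 * sum(etay - lse)
  compute_dic(dev, dhat)
}

#' Deviance information criterion
#'
#' \eqn{\bar D} is the posterior mean deviance, \eqn{p_D = \bar D -
#' D(\bar\theta)} the effective number of parameters, and
#' \eqn{DIC = \bar D + p_D = D(\bar\theta) + 2 p_D}.
#'
#' @param deviance_draws deviance (\eqn{-2 \log L}) at each retained draw.
#' @param deviance_at_mean deviance at the posterior mean of the
#'   parameters.
#' @return named numeric vector \code{Dbar}, \code{Dhat}, \code{pD},
#'   \code{DIC}.
#' @export
compute_dic <- function(deviance_draws, deviance_at_mean) {
  if (!length(deviance_draws)) stop("empty deviance draws")
  dbar <- mean(deviance_draws)
  pd <- dbar - deviance_at_mean
  c(Dbar = dbar, Dhat = deviance_at_mean, pD = pd, DIC = dbar + pd)
}

#' Posterior summaries of region and PSU effects
#'
#' @param fit a \code{\link{star_mnl}} fit.
#' @return data.frame with the unit id, category \code{k}, posterior
#'   \code{median}, \code{q2.5} and \code{q97.5}.
#' @export
region_effects <- function(fit) {
  stopifnot(inherits(fit, "star_mnl"))
  if (!fit$has$spatial) stop("fit has no structured region effect")
  s <- fit$summary$s
  data.frame(region = rep(fit$design$region_ids, 2L),
             k = rep(1:2, each = length(fit$design$region_ids)),
             s[c("median", "q2.5", "q97.5")],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname region_effects
#' @export
psu_effects <- function(fit) {
  stopifnot(inherits(fit, "star_mnl"))
  if (!fit$has$psu) stop("fit has no PSU effect")
  b <- fit$summary$b
  data.frame(psu = rep(fit$design$psu_ids, 2L),
             k = rep(1:2, each = length(fit$design$psu_ids)),
             b[c("median", "q2.5", "q97.5")],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Posterior draws of the fitted age smooth on a grid
#' @param fit a \code{\link{star_mnl}} fit with an \code{s()} term.
#' @param grid ages at which to evaluate; defaults to the observed span.
#' @return list with \code{grid} and per-category summary data.frames.
#' @export
age_effect <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "star_mnl"))
  if (!fit$has$spline) stop("fit has no age smooth")
  span <- attr(fit$design$B, "span")
  if (is.null(grid)) grid <- seq(span[1], span[2], length.out = 101)
  Bg <- bspline_basis(grid, knots = fit$settings$knots,
                      degree = fit$settings$degree, span = span)
  g <- pooled_draws(fit, "gamma")
  M <- ncol(fit$design$B)
  out <- lapply(1:2, function(k) {
    fdraws <- g[, (k - 1L) * M + seq_len(M), drop = FALSE] %*% t(Bg)
    sm <- summarize_posterior(fdraws)
    sm$parameter <- NULL
    cbind(age = grid, sm)
  })
  names(out) <- c("k1", "k2")
  out
}

#' @export
print.star_mnl <- function(x, ...) {
  st <- x$settings
  nkeep <- (st$iterations - st$burnin) / st$thin
  cat("Multinomial-logit structured additive regression (", x$model,
      " model)\n", sep = "")
  cat(sprintf("  %d respondents in categories 1-3; reference category k = 3\n",
              length(x$design$y)))
  cat(sprintf("  %d chain(s) x %d iterations (burn-in %d, thinning %d): %d retained draws each\n",
              st$chains, st$iterations, st$burnin, st$thin, nkeep))
  cat("  terms: fixed effects",
      if (x$has$spline) "+ P-spline age smooth",
      if (x$has$psu) "+ iid PSU effects",
      if (x$has$spatial) "+ MRF region effects", "\n")
  cat(sprintf("  DIC = %.1f (Dbar = %.1f, pD = %.1f)\n",
              x$dic["DIC"], x$dic["Dbar"], x$dic["pD"]))
  invisible(x)
}

#' @export
summary.star_mnl <- function(object, ...) {
  out <- list(model = object$model, beta = object$summary$beta,
              tau2 = object$summary$tau2, dic = object$dic,
              settings = object$settings)
  class(out) <- "summary.star_mnl"
  out
}

#' @export
print.summary.star_mnl <- function(x, ...) {
  cat("Fixed effects (posterior median and 95% credible interval;",
      "or_* columns are relative odds ratios vs the reference category):\n")
  print(x$beta, digits = 3)
  cat("\nVariance parameters:\n")
  print(x$tau2, digits = 3)
  cat(sprintf("\nDIC = %.1f (Dbar = %.1f, Dhat = %.1f, pD = %.1f) [%s model]\n",
              x$dic["DIC"], x$dic["Dbar"], x$dic["Dhat"], x$dic["pD"], x$model))
  invisible(x)
}

#' @export
coef.star_mnl <- function(object, ...) {
  m <- matrix(object$summary$beta$median, ncol = 2L,
              dimnames = list(colnames(object$design$X), c("k1", "k2")))
  m
}

#' @export
fitted.star_mnl <- function(object, ...) {
  des <- object$design
  cm <- function(block) {
    d <- pooled_draws(object, block)
    if (is.null(d)) return(NULL)
    matrix(colMeans(d), ncol = 2L)
  }
  beta <- cm("beta")
  eta <- vapply(1:2, function(k) {
    e <- drop(des$X %*% beta[, k])
    if (object$has$spline) e <- e + drop(des$B %*% cm("gamma")[, k])
    if (object$has$psu) e <- e + cm("b")[des$psu_index, k]
    if (object$has$spatial) e <- e + cm("s")[des$region_index, k]
    e
  }, numeric(length(des$y)))
  multinomial_probs(eta[, 1], eta[, 2])
}

#' @export
residuals.star_mnl <- function(object, ...) {
  P <- fitted(object)
  Y <- matrix(0L, length(object$design$y), 3L)
  Y[cbind(seq_along(object$design$y), object$design$y)] <- 1L
  Y - P
}

#' @export
plot.star_mnl <- function(x, which = c("age", "trace"), ...) {
  which <- match.arg(which)
  if (which == "age" && x$has$spline) {
    ae <- age_effect(x)
    oldpar <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(oldpar))
    for (k in 1:2) {
      sm <- ae[[k]]
      plot(sm$age, sm$median, type = "l",
           ylim = range(sm$q2.5, sm$q97.5),
           xlab = "age", ylab = sprintf("f_%d(age)", k),
           main = sprintf("Age smooth, k = %d", k), ...)
      graphics::lines(sm$age, sm$q2.5, lty = 2)
      graphics::lines(sm$age, sm$q97.5, lty = 2)
      graphics::abline(h = 0, col = "grey")
    }
  } else {
    dev <- unlist(lapply(x$chains, `[[`, "deviance"))
    plot(dev, type = "l", xlab = "retained draw", ylab = "deviance",
         main = "Deviance trace", ...)
  }
  invisible(x)
}
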