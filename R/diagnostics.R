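#' Spectral density of a chain at frequency zero
#'
#' Estimated by fitting an AR model by AIC (Yule-Walker) and evaluating its
#' spectrum at zero, \code{var.pred / (1 - sum(ar))^2}; this is the
#' standard time-series estimator for the asymptotic variance of an MCMC
#' sample mean (\code{spectrum0(x)/length(x)}).
#'
#' @param x numeric chain.
#' @return scalar spectral density at zero.
#' @export
spectrum0 <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 5L) stop("chain too short for spectral estimation")
  if (stats::var(x) == 0) stop("constant chain: zero spectral density")
  fit <- stats::ar(x, aic = TRUE, order.max = min(length(x) - 1L,
                                                  floor(10 * log10(length(x)))))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Effective sample size of a chain
#' @param x numeric chain.
#' @return scalar; \code{length(x) * var(x) / spectrum0(x)}.
#' @export
effective_size <- function(x) {
  length(x) * stats::var(x) / spectrum0(x)
}

#' Geweke convergence diagnostic
#'
#' z-score comparing the mean of the first \code{first} fraction of a
#' (post-burn-in) chain against the mean of the last \code{last} fraction,
#' with standard errors from the spectral density at zero of each window:
#' \deqn{z = (\bar x_A - \bar x_B) / \sqrt{s_A/n_A + s_B/n_B}.}
#' Under convergence z is approximately standard normal; values outside
#' (-1.96, 1.96) flag the chain.
#'
#' @param chain numeric vector of retained draws.
#' @param first,last window fractions (defaults 0.10 and 0.50); they must
#'   not overlap.
#' @return scalar z-score.
#' @export
geweke_z <- function(chain, first = 0.10, last = 0.50) {
  n <- length(chain)
  if (first <= 0 || last <= 0 || first + last > 1)
    stop("window fractions must be positive and non-overlapping")
  nA <- floor(first * n)
  nB <- floor(last * n)
  if (nA < 5L || nB < 5L) stop("chain too short for the requested windows")
  a <- chain[seq_len(nA)]
  b <- chain[seq.int(n - nB + 1L, n)]
  (mean(a) - mean(b)) / sqrt(spectrum0(a) / nA + spectrum0(b) / nB)
}

#' Gelman-Rubin potential scale reduction factors
#'
#' Between/within-chain variance decomposition across parallel chains run
#' from different seeds.  For each parameter the point estimate is
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \, W + B/n}{W} \cdot \frac{d+3}{d+1}}}
#' with a 97.5\% upper quantile from the F-approximation to the ratio, and
#' the multivariate PSRF over all parameters uses the largest eigenvalue of
#' \eqn{W^{-1} B / n}.
#'
#' @param chains list of equal-length numeric matrices (draws x
#'   parameters), one per chain; at least two chains.
#' @return list of class \code{psrf}: \code{psrf} (data.frame with
#'   \code{parameter}, \code{point}, \code{upper}) and \code{multivariate}
#'   (scalar, \code{NA} when a single parameter).
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least two chains")
  chains <- lapply(chains, as.matrix)
  n <- nrow(chains[[1]])
  p <- ncol(chains[[1]])
  if (!all(vapply(chains, nrow, integer(1)) == n) ||
      !all(vapply(chains, ncol, integer(1)) == p))
    stop("chains must have identical dimensions")
  m <- length(chains)

  means <- vapply(chains, colMeans, numeric(p))          # p x m
  vars <- vapply(chains, function(x) apply(x, 2, stats::var), numeric(p))
  means <- matrix(means, p, m); vars <- matrix(vars, p, m)
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  sig2 <- (n - 1) / n * W + B / n
  # sampling-variance correction (Gelman & Rubin 1992)
  Vhat <- sig2 + B / (m * n)
  var_W <- apply(vars, 1, stats::var) / m
  var_B <- 2 * B^2 / (m - 1)
  cov_WB <- vapply(seq_len(p), function(i) {
    (n / m) * (stats::cov(vars[i, ], means[i, ]^2) -
                 2 * mean(means[i, ]) * stats::cov(vars[i, ], means[i, ]))
  }, numeric(1))
  var_V <- ((n - 1) / n)^2 * var_W + ((m + 1) / (m * n))^2 * var_B +
    2 * ((n - 1) * (m + 1) / (m * n^2)) * cov_WB
  df <- 2 * Vhat^2 / var_V
  df[!is.finite(df) | df <= 0] <- Inf      # degenerate (e.g. identical chains)
  corr <- ifelse(is.finite(df), (df + 3) / (df + 1), 1)
  df2 <- 2 * W^2 * m / var_W
  df2[!is.finite(df2) | df2 <= 0] <- Inf
  R2 <- (Vhat / W) * corr
  R2_upper <- (((n - 1) / n) + ((m + 1) / (m * n)) *
                 stats::qf(0.975, m - 1, df2) * (B / n) / W) * corr
  nm <- colnames(chains[[1]]) %||% paste0("par", seq_len(p))
  psrf <- data.frame(parameter = nm,
                     point = sqrt(pmax(R2, 0)),
                     upper = sqrt(pmax(R2_upper, R2, 0)),
                     row.names = NULL, stringsAsFactors = FALSE)

  mpsrf <- NA_real_
  if (p > 1L) {
    Wm <- Reduce(`+`, lapply(chains, stats::cov)) / m
    mu <- rowMeans(means)
    Bm <- matrix(0, p, p)
    for (c in seq_len(m)) Bm <- Bm + tcrossprod(means[, c] - mu)
    Bm <- n * Bm / (m - 1)
    ev <- tryCatch(
      max(Re(eigen(solve(Wm, Bm / n), only.values = TRUE)$values)),
      error = function(e) NA_real_)
    mpsrf <- sqrt((n - 1) / n + (m + 1) / m * ev)
  }
  structure(list(psrf = psrf, multivariate = mpsrf), class = "psrf")
}

#' @export
print.psrf <- function(x, ...) {
  cat("Gelman-Rubin potential scale reduction factors:\n")
  print(x$psrf, digits = 4)
  if (!is.na(x$multivariate))
    cat(sprintf("multivariate PSRF: %.4f\n", x$multivariate))
  invisible(x)
}

#' Convergence diagnostics for a fitted model
#'
#' Computes Geweke z-scores for every fixed-effect chain (2 x 8 scores for
#' the standard model) and, when the fit holds several chains,
#' Gelman-Rubin PSRFs with the multivariate factor over the fixed-effect
#' block.
#'
#' @param fit a \code{\link{star_mnl}} fit.
#' @param z_threshold absolute Geweke bound (default 1.96).
#' @param psrf_threshold bound on the 97.5\% PSRF quantile (default 1.02).
#' @param blocks which parameter blocks to report (default \code{"beta"}).
#' @return data.frame of diagnostics with pass/fail flags, plus the
#'   multivariate PSRF as attribute \code{mpsrf}.
#' @export
diagnose <- function(fit, z_threshold = 1.96, psrf_threshold = 1.02,
                     blocks = "beta") {
  stopifnot(inherits(fit, "star_mnl"))
  out <- NULL
  mpsrf <- NA_real_
  for (block in blocks) {
    per_chain <- lapply(seq_along(fit$chains), function(ch) {
      f2 <- fit; f2$chains <- fit$chains[ch]
      d <- pooled_draws(f2, block)
      colnames(d) <- block_names(fit, block)
      d
    })
    pooled <- do.call(rbind, per_chain)
    z <- apply(per_chain[[1]], 2, geweke_z)
    res <- data.frame(block = block, parameter = colnames(pooled),
                      geweke_z = z, geweke_pass = abs(z) < z_threshold,
                      row.names = NULL, stringsAsFactors = FALSE)
    if (length(fit$chains) >= 2L) {
      gr <- gelman_rubin(per_chain)
      res$psrf <- gr$psrf$point
      res$psrf_upper <- gr$psrf$upper
      res$psrf_pass <- gr$psrf$upper < psrf_threshold
      if (block == "beta") mpsrf <- gr$multivariate
    }
    out <- rbind(out, res)
  }
  attr(out, "mpsrf") <- mpsrf
  out
}
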