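educ_levels <- function() c("none", "primary", "secondary+")
income_levels <- function() c("poorest", "poorer", "middle", "richer", "richest")

# 8-column fixed-effect matrix: intercept; urban; educ primary, secondary+;
# income poorer, middle, richer, richest (references rural / none / poorest)
covariate_matrix <- function(data) {
  n <- nrow(data)
  for (v in c("age", "urban", "educ", "income"))
    if (is.null(data[[v]])) stop("missing covariate column: ", v)
  urban <- data$urban
  if (!all(urban %in% c(0, 1)))
    stop("urban must be a 0/1 indicator (respondent ",
         data$resp_id[which(!urban %in% c(0, 1))[1]], ")")
  ed <- match(as.character(data$educ), educ_levels())
  if (anyNA(ed)) {
    i <- which(is.na(ed))[1]
    stop("unknown educ level '", data$educ[i], "' for respondent ",
         if (!is.null(data$resp_id)) data$resp_id[i] else i)
  }
  inc <- match(as.character(data$income), income_levels())
  if (anyNA(inc)) {
    i <- which(is.na(inc))[1]
    stop("unknown income level '", data$income[i], "' for respondent ",
         if (!is.null(data$resp_id)) data$resp_id[i] else i)
  }
  X <- cbind(1, as.numeric(urban),
             as.numeric(ed == 2L), as.numeric(ed == 3L),
             as.numeric(inc == 2L), as.numeric(inc == 3L),
             as.numeric(inc == 4L), as.numeric(inc == 5L))
  colnames(X) <- c("(Intercept)", "urban", "educ_primary", "educ_secondary+",
                   "income_poorer", "income_middle", "income_richer",
                   "income_richest")
  X
}

#' Cubic B-spline basis on equidistant knots
#'
#' Degree-3 B-spline design matrix whose knot grid divides
#' \code{[min(ages), max(ages)]} into \code{knots} equal intervals, with the
#' boundary knots extended outward at the same spacing.  The basis therefore
#' has exactly \code{M = knots + degree} columns and its rows form a
#' partition of unity on the span.
#'
#' @param ages numeric vector; values outside the span are clamped to the
#'   boundary with a warning.
#' @param knots number of equidistant inter-knot intervals (default 20).
#' @param degree spline degree (default 3).
#' @param span optional length-2 numeric giving the knot span; defaults to
#'   \code{range(ages)}.
#' @return n x M matrix with the knot span attached as attribute
#'   \code{span} and the full knot sequence as attribute \code{knots}.
#' @export
bspline_basis <- function(ages, knots = 20L, degree = 3L, span = NULL) {
  knots <- as.integer(knots); degree <- as.integer(degree)
  if (knots < degree + 1L) stop("need at least degree + 1 knot intervals")
  if (is.null(span)) span <- range(ages)
  if (span[2] <= span[1]) span <- span[1] + c(-0.5, 0.5)  # constant input
  if (any(ages < span[1] | ages > span[2])) {
    warning("ages outside the knot span clamped to the boundary")
    ages <- pmin(pmax(ages, span[1]), span[2])
  }
  h <- (span[2] - span[1]) / knots
  kseq <- seq(span[1] - degree * h, span[2] + degree * h, by = h)
  B <- splines::splineDesign(kseq, ages, ord = degree + 1L, outer.ok = FALSE)
  stopifnot(ncol(B) == knots + degree)
  colnames(B) <- paste0("B", seq_len(ncol(B)))
  attr(B, "span") <- span
  attr(B, "knots") <- kseq
  B
}

# second-difference penalty: (M-2) x M matrix D2 with K = t(D2) %*% D2
rw2_penalty <- function(M) {
  D2 <- diff(diag(M), differences = 2L)
  crossprod(D2)
}

#' Multinomial logit probabilities for a three-category outcome
#'
#' Converts linear predictors of categories 1 and 2 (category 3 is the
#' reference with predictor 0) into probabilities
#' \eqn{\pi_k = e^{\eta_k} / (1 + e^{\eta_1} + e^{\eta_2})} for k = 1, 2 and
#' \eqn{\pi_3} as the remainder, computed overflow-safely.
#'
#' @param eta1,eta2 numeric vectors of linear predictors.
#' @return n x 3 matrix of probabilities with rows summing to 1.
#' @export
multinomial_probs <- function(eta1, eta2) {
  stopifnot(length(eta1) == length(eta2))
  m <- pmax(0, eta1, eta2)
  e0 <- exp(-m); e1 <- exp(eta1 - m); e2 <- exp(eta2 - m)
  denom <- e0 + e1 + e2
  cbind(p1 = e1 / denom, p2 = e2 / denom, p3 = e0 / denom)
}

#' Design matrices for the structured additive multinomial model
#'
#' Builds from a respondent table and its category labels everything the
#' sampler needs: the 8-column fixed-effect matrix (dummy coding against
#' references rural / no education / poorest quintile), the age B-spline
#' basis, PSU and region index maps, and one-hot outcome indicators.
#' Respondents outside categories 1-3 are dropped (the model stage uses
#' only the three dominant categories).
#'
#' @param data respondent table (survey header columns).
#' @param labels integer category labels, one per row of \code{data}; if
#'   omitted, a \code{category} column of \code{data} is used.
#' @param graph optional \code{\link{region_graph}}; when given, region
#'   indices refer to its ordering and unknown regions are an error.
#' @param knots,degree passed to \code{\link{bspline_basis}}.
#' @return list of class \code{star_design}: \code{X}, \code{B},
#'   \code{psu_index}, \code{region_index}, \code{Y} (n x 3 one-hot),
#'   \code{y} (labels), \code{psu_ids}, \code{region_ids}, \code{age},
#'   \code{keep} (row indices of \code{data} retained).
#' @export
build_design <- function(data, labels = data$category, graph = NULL,
                         knots = 20L, degree = 3L) {
  if (is.null(labels)) stop("category labels required (argument or 'category' column)")
  labels <- as.integer(labels)
  if (length(labels) != nrow(data)) stop("one label per respondent required")
  keep <- which(labels %in% 1:3)
  data <- data[keep, , drop = FALSE]
  labels <- labels[keep]
  if (!nrow(data)) stop("no respondents in categories 1-3")

  X <- covariate_matrix(data)
  B <- bspline_basis(data$age, knots = knots, degree = degree)

  psu_ids <- sort(unique(data$psu))
  psu_index <- match(data$psu, psu_ids)
  if (is.null(graph)) {
    region_ids <- sort(unique(as.character(data$region)))
  } else {
    region_ids <- graph$region_ids
    if (any(!as.character(data$region) %in% region_ids))
      stop("region in data absent from graph: ",
           setdiff(as.character(data$region), region_ids)[1])
  }
  region_index <- match(as.character(data$region), region_ids)

  Y <- matrix(0L, nrow(data), 3L)
  Y[cbind(seq_len(nrow(data)), labels)] <- 1L

  structure(list(X = X, B = B, psu_index = psu_index,
                 region_index = region_index, Y = Y, y = labels,
                 psu_ids = psu_ids, region_ids = region_ids,
                 age = data$age, keep = keep),
            class = "star_design")
}

#' Multinomial log-likelihood of a parameter state
#'
#' Evaluates \eqn{\sum_i \sum_k Y_{ik} \log \pi_{ik}} where the linear
#' predictors are assembled from the full structured additive state
#' (fixed effects, spline, PSU and region effects); guarded against
#' underflow via the log-sum-exp form.
#'
#' @param design a \code{\link{build_design}} result.
#' @param beta 8 x 2 coefficient matrix.
#' @param gamma M x 2 spline coefficients (or \code{NULL} to omit).
#' @param b PSU effects, one row per PSU, 2 columns (or \code{NULL}).
#' @param s region effects, one row per region, 2 columns (or \code{NULL}).
#' @return scalar log-likelihood.
#' @export
star_loglik <- function(design, beta, gamma = NULL, b = NULL, s = NULL) {
  eta <- vapply(1:2, function(k) {
    e <- drop(design$X %*% beta[, k])
    if (!is.null(gamma)) e <- e + drop(design$B %*% gamma[, k])
    if (!is.null(b)) e <- e + b[design$psu_index, k]
    if (!is.null(s)) e <- e + s[design$region_index, k]
    e
  }, numeric(nrow(design$X)))
  eta <- matrix(eta, ncol = 2L)   # vapply drops dims when n = 1
  m <- pmax(0, eta[, 1], eta[, 2])
  lse <- m + log(exp(-m) + exp(eta[, 1] - m) + exp(eta[, 2] - m))
  etay <- ifelse(design$y == 3L, 0, eta[cbind(seq_along(design$y),
                                              pmin(design$y, 2L))])
  sum(etay - lse)
}
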