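#' PSU-level empowerment-category proportions
#'
#' Tabulates, for every PSU, how many respondents fall in each of the three
#' dominant categories and the corresponding proportions.  Categories 4 and
#' 5 are excluded from both numerator and denominator; PSUs whose
#' respondents all fall outside categories 1-3 are flagged
#' (\code{empty = TRUE}, proportions \code{NA}).
#'
#' @param labels integer category labels, one per respondent.
#' @param data respondent table with \code{psu}, \code{region}, \code{lon},
#'   \code{lat} columns.
#' @return data.frame with one row per PSU: \code{psu}, \code{region},
#'   \code{lon}, \code{lat}, counts \code{n1..n3}, proportions
#'   \code{p1..p3}, \code{empty}, and \code{hex_color} from
#'   \code{\link{blend_rgb}}.
#' @export
psu_proportions <- function(labels, data) {
  labels <- as.integer(labels)
  if (length(labels) != nrow(data)) stop("one label per respondent required")
  psus <- sort(unique(data$psu))
  idx <- match(data$psu, psus)
  counts <- matrix(0L, length(psus), 3L)
  for (k in 1:3) {
    t_k <- tapply(labels == k, idx, sum)
    counts[as.integer(names(t_k)), k] <- as.integer(t_k)
  }
  tot <- rowSums(counts)
  p <- counts / ifelse(tot > 0, tot, NA_real_)
  first <- !duplicated(idx)
  meta <- data[first, c("psu", "region", "lon", "lat")]
  meta <- meta[match(psus, meta$psu), ]
  ok <- tot > 0
  hex <- rep(NA_character_, length(psus))
  if (any(ok)) {
    rgb <- blend_rgb(p[ok, 1], p[ok, 2], p[ok, 3])
    hex[ok] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  }
  data.frame(meta,
             n1 = counts[, 1], n2 = counts[, 2], n3 = counts[, 3],
             p1 = p[, 1], p2 = p[, 2], p3 = p[, 3],
             empty = !ok, hex_color = hex,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tri-colour blend of category proportions
#'
#' Maps the three category proportions of a PSU to an RGB colour: blue
#' carries category 1 ("more empowered"), red category 2 ("less
#' empowered") and green category 3 ("modal empowered"), so
#' \code{(r, g, b) = round(255 * (p2, p3, p1))}.
#'
#' @param p1,p2,p3 proportions summing to 1 (within 1e-9), vectorised.
#' @return integer matrix with columns \code{r}, \code{g}, \code{b} in
#'   0-255.
#' @export
blend_rgb <- function(p1, p2, p3) {
  tot <- p1 + p2 + p3
  if (any(abs(tot - 1) > 1e-9) || any(c(p1, p2, p3) < 0))
    stop("proportions must be nonnegative and sum to 1")
  cbind(r = as.integer(round(255 * p2)),
        g = as.integer(round(255 * p3)),
        b = as.integer(round(255 * p1)))
}

#' Moran's I spatial autocorrelation
#'
#' Global Moran's I with row-standardised weights:
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \frac{\sum_{ij} w_{ij} (x_i - \bar
#' x)(x_j - \bar x)}{\sum_i (x_i - \bar x)^2}.}
#' Under spatial randomness its expectation is \eqn{-1/(n-1)}.
#'
#' @param values numeric vector, one value per spatial unit; must not be
#'   constant.
#' @param weights nonnegative square weight matrix with zero diagonal
#'   (e.g. \code{\link{region_weights}} or \code{\link{knn_weights}});
#'   units with an empty weight row are dropped with a warning.
#' @return scalar Moran's I.
#' @export
morans_i <- function(values, weights) {
  weights <- as.matrix(weights)
  n <- length(values)
  if (nrow(weights) != n || ncol(weights) != n)
    stop("weights must be an n x n matrix")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (any(diag(weights) != 0)) stop("weights must have a zero diagonal")
  rs <- rowSums(weights)
  if (any(rs == 0)) {
    warning(sum(rs == 0), " unit(s) with empty weight rows dropped")
    keep <- rs > 0
    values <- values[keep]
    weights <- weights[keep, keep, drop = FALSE]
    rs <- rowSums(weights)
    if (any(rs == 0)) stop("weights still contain empty rows after dropping")
    n <- length(values)
  }
  if (n < 3L) stop("need at least 3 units")
  x <- values - mean(values)
  if (sum(x^2) == 0) stop("constant values: Moran's I undefined")
  W <- weights / rs   # row-standardised
  (n / sum(W)) * sum(W * outer(x, x)) / sum(x^2)
}

#' Binary k-nearest-neighbour weights for point locations
#'
#' Symmetrised 0/1 weights in which \code{w[i, j] = 1} when j is among the
#' k nearest points to i (great-circle distance) or vice versa.
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param k number of neighbours (default 10).
#' @return n x n 0/1 matrix with zero diagonal.
#' @export
knn_weights <- function(lon, lat, k = 10L) {
  n <- length(lon)
  if (n <= k) stop("need more points than neighbours")
  D <- geosphere::distm(cbind(lon, lat))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    W[i, ord[ord != i][seq_len(k)]] <- 1
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  W
}

#' Residual spatial dependence of the PSU effects
#'
#' The model's unstructured PSU effects should carry the left-over spatial
#' signal; this helper measures it with Moran's I in either of two labelled
#' modes: \code{"region"} aggregates PSU-wise posterior medians to region
#' medians and uses first-order region adjacency (the aggregation used to
#' map PSU effects at region scale), and \code{"knn"} works directly on PSU
#' points with symmetrised binary k-nearest-neighbour weights.
#'
#' @param fit a \code{\link{star_mnl}} fit with \code{re(psu)} effects.
#' @param data respondent table the model was fitted to (for PSU
#'   coordinates and regions).
#' @param graph \code{\link{region_graph}} (required for
#'   \code{mode = "region"}).
#' @param mode \code{"region"} (default) or \code{"knn"}.
#' @param k neighbours for \code{mode = "knn"}.
#' @return data.frame with columns \code{k} (category), \code{mode} and
#'   \code{morans_i}.
#' @export
morans_psu_effects <- function(fit, data, graph = NULL,
                               mode = c("region", "knn"), k = 10L) {
  mode <- match.arg(mode)
  eff <- psu_effects(fit)
  d2 <- data[fit$design$keep, , drop = FALSE]
  first <- !duplicated(d2$psu)
  psu_meta <- d2[first, c("psu", "region", "lon", "lat")]
  out <- lapply(1:2, function(kk) {
    e <- eff[eff$k == kk, ]
    e <- merge(e, psu_meta, by = "psu")
    if (mode == "region") {
      if (is.null(graph)) stop("mode = 'region' requires the adjacency graph")
      med <- tapply(e$median, as.character(e$region), stats::median)
      vals <- as.numeric(med[graph$region_ids])
      keep <- !is.na(vals)
      W <- region_weights(graph)[keep, keep, drop = FALSE]
      I <- morans_i(vals[keep], W)
    } else {
      I <- morans_i(e$median, knn_weights(e$lon, e$lat, k = k))
    }
    data.frame(k = kk, mode = mode, morans_i = I, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
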