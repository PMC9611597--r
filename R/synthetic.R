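#' Ground truth for survey simulation
#'
#' Bundles the generating values of the structured additive predictor used
#' by \code{\link{simulate_survey}}: fixed-effect coefficients, smooth age
#' effects, the standard deviations generating PSU and region effects, and
#' the item flip-noise probability.
#'
#' Defaults are chosen to mimic the qualitative pattern seen in empowerment
#' surveys: education and urban residence push respondents toward category 1
#' ("more empowered") and away from category 2 ("less empowered") relative
#' to the modal reference, with a smooth non-monotone age effect, moderate
#' PSU-level clustering and a strong spatially structured region effect.
#'
#' @param beta 8 x 2 matrix of fixed-effect coefficients (rows: intercept,
#'   urban, educ primary, educ secondary+, income poorer/middle/richer/
#'   richest; columns: categories k = 1, 2).
#' @param age_fn list of two functions of age (years), one per category;
#'   should be centred over the sampled age range so intercepts stay
#'   identified.
#' @param psu_sd standard deviation of iid PSU effects.
#' @param region_sd conditional standard deviation of the intrinsic MRF
#'   generating region effects (\code{tau2 = region_sd^2}).
#' @param epsilon item flip-noise probability in [0, 1].
#' @param s optional J x 2 matrix of fixed region effects (each column
#'   summing to zero); if \code{NULL} they are drawn from the intrinsic
#'   GMRF at simulation time.
#' @return list of class \code{ground_truth}.
#' @export
ground_truth <- function(beta = default_truth_beta(),
                         age_fn = default_truth_age_fn(),
                         psu_sd = 0.3, region_sd = 0.6,
                         epsilon = 0.05, s = NULL) {
  beta <- as.matrix(beta)
  if (!all(dim(beta) == c(8L, 2L))) stop("beta must be an 8 x 2 matrix")
  if (!is.list(age_fn) || length(age_fn) != 2L ||
      !all(vapply(age_fn, is.function, logical(1))))
    stop("age_fn must be a list of two functions")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  if (psu_sd < 0 || region_sd < 0) stop("standard deviations must be nonnegative")
  if (!is.null(s)) {
    s <- as.matrix(s)
    if (ncol(s) != 2L) stop("s must have one column per category k = 1, 2")
    if (max(abs(colSums(s))) > 1e-8) stop("region effects must sum to zero")
  }
  structure(list(beta = beta, age_fn = age_fn, psu_sd = psu_sd,
                 region_sd = region_sd, epsilon = epsilon, s = s),
            class = "ground_truth")
}

#' @rdname ground_truth
#' @export
default_truth_beta <- function() {
  cbind(c(0.2, 0.4, 0.3, 0.7, 0.1, 0.2, 0.3, 0.5),
        c(-0.1, -0.5, -0.3, -0.8, -0.1, -0.2, -0.4, -0.6))
}

#' @rdname ground_truth
#' @export
default_truth_age_fn <- function() {
  # both centred exactly over uniform integer ages 15..49
  list(function(a) 0.4 * (((a - 32) / 17)^2 - 102 / 289),
       function(a) -0.3 * sin(2 * pi * (a - 15) / 34))
}

#' Emit noisy responses from a category template
#'
#' Starts from the category's response template and, independently with
#' probability \code{epsilon}, replaces each of the ten items by a uniformly
#' chosen different admissible level.  The number of changed items is thus
#' Binomial(10, epsilon).
#'
#' @param category integer in 1..nrow(templates).
#' @param templates template table, default \code{\link{default_templates}}.
#' @param epsilon flip probability in [0, 1].
#' @param n number of response vectors to draw.
#' @return data.frame of \code{n} response vectors.
#' @export
emit_responses <- function(category, templates = default_templates(),
                           epsilon = 0, n = 1L) {
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  templates <- validate_responses(templates)
  if (!(category %in% seq_len(nrow(templates))))
    stop("no template for category ", category)
  emit_bulk(rep.int(as.integer(category), n), templates, epsilon)
}

# vectorised template + flip-noise sampler
emit_bulk <- function(labels, templates, epsilon) {
  lv <- empowerment_items()
  out <- templates[labels, , drop = FALSE]
  rownames(out) <- NULL
  n <- length(labels)
  for (it in names(lv)) {
    flip <- stats::runif(n) < epsilon
    if (any(flip)) {
      levels <- lv[[it]]
      cur <- out[[it]][flip]
      # uniform over the other admissible levels: shift a 1..(L-1) draw past cur
      r <- sample.int(length(levels) - 1L, sum(flip), replace = TRUE)
      pos <- match(cur, levels)
      newpos <- r + (r >= pos)
      out[[it]][flip] <- levels[newpos]
    }
  }
  out
}

#' Simulate a hierarchical two-stage survey
#'
#' Generates a DHS-like dataset: regions from an adjacency graph, several
#' PSUs (primary sampling units) per region, 15-100 respondents per PSU,
#' sociodemographic covariates, a three-category outcome drawn from the
#' multinomial-logit structured additive model at the supplied ground
#' truth, and ten categorical items emitted from the category templates
#' with flip noise.  PSU coordinates are the PSU location displaced by a
#' random jitter of at most 2 km in urban and 5 km in rural PSUs
#' (direction uniform, distance uniform up to the cap), emulating the
#' displacement applied to published survey coordinates.
#'
#' @param graph a \code{\link{region_graph}}; lattice graphs carry cell
#'   coordinates used to lay out region centroids (1 degree spacing).
#' @param truth a \code{\link{ground_truth}}.
#' @param psus_per_region number of PSUs in each region (scalar or vector
#'   of length J).
#' @param respondents_per_psu integer range \code{c(min, max)}; counts are
#'   drawn uniformly within it.
#' @param covariate_config list with elements \code{urban_prob} (PSU-level
#'   probability of urban residence), \code{educ_probs} (length-3
#'   probabilities for none/primary/secondary+, or J x 3 matrix for
#'   region-varying composition), \code{income_probs} (length-5 or J x 5).
#'   Region-varying entries let covariate composition confound space.
#' @param include_minor_categories also emit the two minor categories
#'   ("autonomous", "other") from their templates, at rates
#'   \code{minor_shares}, to exercise the full k = 5 clustering stage.
#' @param minor_shares rates for categories 4 and 5 when included.
#' @param seed optional integer seed.
#' @return list with \code{data} (respondent table with the fixed survey
#'   header), \code{truth} (the input truth augmented with the realised
#'   region effects \code{s}, PSU effects \code{b}, PSU table and the
#'   generating labels), suitable for recovery tests.
#' @export
simulate_survey <- function(graph, truth = ground_truth(),
                            psus_per_region = 6L,
                            respondents_per_psu = c(15L, 100L),
                            covariate_config = list(),
                            include_minor_categories = FALSE,
                            minor_shares = c(0.06, 0.006),
                            seed = NULL) {
  stopifnot(inherits(graph, "region_graph"), inherits(truth, "ground_truth"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  J <- length(graph$region_ids)
  psus_per_region <- rep_len(as.integer(psus_per_region), J)
  if (any(psus_per_region < 1L)) stop("every region needs at least one PSU")
  rng <- as.integer(respondents_per_psu)
  if (length(rng) != 2L || rng[1] < 1L || rng[2] < rng[1])
    stop("respondents_per_psu must be an increasing positive range")

  cfg <- utils::modifyList(
    list(urban_prob = 0.4,
         educ_probs = c(0.5, 0.3, 0.2),
         income_probs = rep(0.2, 5)),
    covariate_config)

  # region centroid layout: lattice coords when available, else a grid by index
  coords <- attr(graph, "coords")
  if (is.null(coords)) {
    side <- ceiling(sqrt(J))
    coords <- cbind(row = (seq_len(J) - 1L) %/% side + 1L,
                    col = (seq_len(J) - 1L) %% side + 1L)
  }
  cell <- 1.0  # degrees between region centroids
  cen_lon <- -10 + (coords[, "col"] - 1L) * cell
  cen_lat <- 5 + (max(coords[, "row"]) - coords[, "row"]) * cell

  # region effects
  s <- truth$s
  if (is.null(s))
    s <- cbind(sample_intrinsic_gmrf(graph, truth$region_sd^2),
               sample_intrinsic_gmrf(graph, truth$region_sd^2))

  # PSUs
  U <- sum(psus_per_region)
  psu_region <- rep(seq_len(J), psus_per_region)
  base_lon <- cen_lon[psu_region] + stats::runif(U, -0.4, 0.4) * cell
  base_lat <- cen_lat[psu_region] + stats::runif(U, -0.4, 0.4) * cell
  urban <- stats::rbinom(U, 1L, cfg$urban_prob)
  cap_km <- ifelse(urban == 1L, 2, 5)
  bearing <- stats::runif(U, 0, 360)
  dist_m <- stats::runif(U, 0, cap_km) * 1000
  moved <- geosphere::destPoint(cbind(base_lon, base_lat), bearing, dist_m)
  psu_lon <- moved[, 1]; psu_lat <- moved[, 2]
  b <- matrix(stats::rnorm(U * 2L, 0, truth$psu_sd), U, 2L)

  # respondents
  n_per_psu <- rng[1] + floor(stats::runif(U) * (rng[2] - rng[1] + 1L))
  n <- sum(n_per_psu)
  psu_of <- rep(seq_len(U), n_per_psu)
  region_of <- psu_region[psu_of]
  age <- 15L + floor(stats::runif(n) * 35)

  draw_level <- function(probs, levels) {
    if (is.matrix(probs)) {
      if (!all(dim(probs) == c(J, length(levels))))
        stop("region-varying probabilities must be J x ", length(levels))
      out <- character(n)
      for (j in seq_len(J)) {
        idx <- which(region_of == j)
        if (length(idx))
          out[idx] <- sample(levels, length(idx), replace = TRUE, prob = probs[j, ])
      }
      out
    } else {
      sample(levels, n, replace = TRUE, prob = probs)
    }
  }
  educ <- draw_level(cfg$educ_probs, c("none", "primary", "secondary+"))
  income <- draw_level(cfg$income_probs,
                       c("poorest", "poorer", "middle", "richer", "richest"))

  data <- data.frame(
    resp_id = seq_len(n),
    region = graph$region_ids[region_of],
    psu = psu_of,
    lon = psu_lon[psu_of], lat = psu_lat[psu_of],
    age = age, urban = urban[psu_of],
    educ = educ, income = income,
    stringsAsFactors = FALSE)

  # linear predictors and category draw
  X <- covariate_matrix(data)
  eta1 <- drop(X %*% truth$beta[, 1]) + truth$age_fn[[1]](age) +
    b[psu_of, 1] + s[region_of, 1]
  eta2 <- drop(X %*% truth$beta[, 2]) + truth$age_fn[[2]](age) +
    b[psu_of, 2] + s[region_of, 2]
  P <- multinomial_probs(eta1, eta2)
  u <- stats::runif(n)
  labels <- 1L + (u > P[, 1]) + (u > P[, 1] + P[, 2])

  if (include_minor_categories) {
    v <- stats::runif(n)
    labels[v < minor_shares[1] + minor_shares[2]] <- 4L
    labels[v < minor_shares[2]] <- 5L
  }

  data <- cbind(data, emit_bulk(labels, validate_responses(default_templates()),
                                truth$epsilon))

  truth_out <- truth
  truth_out$s <- s
  truth_out$b <- b
  truth_out$labels <- labels
  truth_out$psu_table <- data.frame(
    psu = seq_len(U), region = graph$region_ids[psu_region],
    lon = psu_lon, lat = psu_lat, urban = urban,
    base_lon = base_lon, base_lat = base_lat,
    jitter_km = dist_m / 1000, stringsAsFactors = FALSE)
  list(data = data, truth = truth_out)
}

survey_header <- function() {
  c("resp_id", "region", "psu", "lon", "lat", "age", "urban", "educ",
    "income", item_names())
}

#' Read and write the respondent table
#'
#' CSV with the fixed header \code{resp_id, region, psu, lon, lat, age,
#' urban, educ, income, v_burns, v_refuse, v_argue, v_neglect, v_goout,
#' d_visit, d_purchase, d_health, d_spend, refuse_sex}.
#'
#' @param data respondent table.
#' @param path file path.
#' @return \code{read_survey} returns the validated data.frame.
#' @export
write_survey <- function(data, path) {
  miss <- setdiff(survey_header(), names(data))
  if (length(miss)) stop("missing survey columns: ", paste(miss, collapse = ", "))
  utils::write.csv(data[survey_header()], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(region = "character"))
  miss <- setdiff(survey_header(), names(data))
  if (length(miss)) stop("missing survey columns: ", paste(miss, collapse = ", "))
  validate_responses(data)  # complete-case / level check
  data
}

#' Serialise ground truth to a JSON sidecar
#'
#' Functions are stored as the age-effect values on the integer age grid
#' 15..49; \code{read_ground_truth} rebuilds step-interpolating functions
#' from them.
#'
#' @param truth a \code{\link{ground_truth}} (possibly augmented by
#'   \code{\link{simulate_survey}}).
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  grid <- 15:49
  obj <- list(beta = truth$beta,
              age_grid = grid,
              age_values = cbind(truth$age_fn[[1]](grid), truth$age_fn[[2]](grid)),
              psu_sd = truth$psu_sd, region_sd = truth$region_sd,
              epsilon = truth$epsilon)
  for (f in c("s", "b", "labels")) if (!is.null(truth[[f]])) obj[[f]] <- truth[[f]]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_fn <- function(grid, vals) {
    force(grid); force(vals)
    function(a) vals[pmin(pmax(round(a), min(grid)), max(grid)) - min(grid) + 1L]
  }
  tr <- ground_truth(beta = matrix(unlist(obj$beta), 8L, 2L),
                     age_fn = list(make_fn(obj$age_grid, obj$age_values[, 1]),
                                   make_fn(obj$age_grid, obj$age_values[, 2])),
                     psu_sd = obj$psu_sd, region_sd = obj$region_sd,
                     epsilon = obj$epsilon)
  for (f in c("s", "b", "labels"))
    if (!is.null(obj[[f]])) tr[[f]] <- if (f == "labels") as.integer(obj[[f]]) else as.matrix(obj[[f]])
  tr
}
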