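#' Default pipeline configuration
#'
#' Settings for a complete simulate - cluster - map - fit - compare -
#' diagnose run at desk scale: a 4 x 4 region lattice, 4 PSUs per region,
#' 15-25 respondents per PSU and short chains.  Every stochastic stage
#' receives its own seed derived from the master seed by a fixed offset
#' (+1 simulate, +2 clustering, +3 full fit, +4 null fit), so stages can be
#' re-run independently and reproducibly.
#'
#' @param seed master seed.
#' @return nested list understood by \code{\link{run_pipeline}}.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       lattice = c(4L, 4L),
       psus_per_region = 4L,
       respondents_per_psu = c(15L, 25L),
       truth = list(),
       include_minor_categories = FALSE,
       kmodes = list(max_iter = 100L),
       model = list(iterations = 2000L, burnin = 500L, thin = 5L,
                    chains = 2L, knots = 20L, degree = 3L))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on synthetic data and persists each
#' stage's artifacts to \code{out}: the survey table and ground-truth
#' sidecar, the region graph, k-modes labels and final modes, the PSU map
#' table, fixed-effect summaries for the full (spatial) and null
#' (non-spatial) models, the DIC comparison, the Moran's I comparison of
#' region-aggregated PSU effects, convergence diagnostics and a run log.
#' The comparison stages consume only persisted artifacts of earlier
#' stages.
#'
#' @param config configuration list; see
#'   \code{\link{default_pipeline_config}}.  Supplied entries override the
#'   defaults.
#' @param out output directory (created if needed).
#' @return invisibly, a list with the fitted objects and artifact paths.
#' @export
run_pipeline <- function(config = list(), out) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_lines <- c(sprintf("starmnl pipeline, R %s.%s", R.version$major, R.version$minor),
                 sprintf("master seed: %d (stage offsets: simulate +1, cluster +2, full fit +3, null fit +4)",
                         cfg$seed))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  path <- function(f) file.path(out, f)

  # -- simulate ----------------------------------------------------------
  graph <- stage("simulate", build_region_lattice(cfg$lattice[1], cfg$lattice[2]))
  truth <- stage("simulate", do.call(ground_truth, cfg$truth))
  sim <- stage("simulate", simulate_survey(
    graph, truth, psus_per_region = cfg$psus_per_region,
    respondents_per_psu = cfg$respondents_per_psu,
    include_minor_categories = isTRUE(cfg$include_minor_categories),
    seed = cfg$seed + 1L))
  write_region_graph(graph, path("regions.gra"))
  write_survey(sim$data, path("survey.csv"))
  write_ground_truth(sim$truth, path("truth.json"))
  log_lines <- c(log_lines, sprintf("simulate: %d respondents, %d PSUs, %d regions",
                                    nrow(sim$data), nrow(sim$truth$psu_table),
                                    length(graph$region_ids)))

  # -- cluster -----------------------------------------------------------
  set.seed(cfg$seed + 2L)
  km <- stage("cluster", kmodes(sim$data, max_iter = cfg$kmodes$max_iter))
  utils::write.csv(data.frame(resp_id = sim$data$resp_id, category = km$cluster),
                   path("labels.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(km$modes, path("modes.csv"), row.names = FALSE, quote = FALSE)
  log_lines <- c(log_lines, sprintf("cluster: sizes %s, cost %d, %s",
                                    paste(km$sizes, collapse = "/"), km$cost,
                                    if (km$converged) "converged" else "not converged"))

  # -- map ---------------------------------------------------------------
  map <- stage("map", psu_proportions(km$cluster, sim$data))
  utils::write.csv(map, path("map.csv"), row.names = FALSE, quote = FALSE)

  # -- fit ---------------------------------------------------------------
  md <- cfg$model
  dat <- sim$data
  dat$category <- km$cluster
  fit_full <- stage("fit full", star_mnl(
    category ~ urban + educ + income + s(age) + re(psu) + mrf(region),
    data = dat, graph = graph,
    iterations = md$iterations, burnin = md$burnin, thin = md$thin,
    chains = md$chains, seed = cfg$seed + 3L,
    knots = md$knots, degree = md$degree))
  fit_null <- stage("fit null", star_mnl(
    category ~ urban + educ + income + s(age) + re(psu),
    data = dat,
    iterations = md$iterations, burnin = md$burnin, thin = md$thin,
    chains = md$chains, seed = cfg$seed + 4L,
    knots = md$knots, degree = md$degree))
  utils::write.csv(fit_full$summary$beta, path("summary_full.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fit_null$summary$beta, path("summary_null.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(region_effects(fit_full), path("region_effects.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cbind(model = "full", psu_effects(fit_full)),
                   path("psu_effects_full.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(cbind(model = "null", psu_effects(fit_null)),
                   path("psu_effects_null.csv"), row.names = FALSE, quote = FALSE)

  # -- compare -----------------------------------------------------------
  dic <- rbind(data.frame(model = "null", t(fit_null$dic)),
               data.frame(model = "full", t(fit_full$dic)))
  utils::write.csv(dic, path("dic_comparison.csv"), row.names = FALSE, quote = FALSE)
  mor <- rbind(cbind(model = "null",
                     morans_psu_effects(fit_null, dat, graph, mode = "region")),
               cbind(model = "full",
                     morans_psu_effects(fit_full, dat, graph, mode = "region")))
  utils::write.csv(mor, path("morans_comparison.csv"), row.names = FALSE, quote = FALSE)
  log_lines <- c(log_lines,
                 sprintf("compare: DIC full %.1f vs null %.1f", fit_full$dic["DIC"],
                         fit_null$dic["DIC"]))

  # -- diagnose ----------------------------------------------------------
  diag <- stage("diagnose", diagnose(fit_full))
  utils::write.csv(diag, path("diagnostics.csv"), row.names = FALSE, quote = FALSE)
  if (!is.na(attr(diag, "mpsrf")))
    log_lines <- c(log_lines, sprintf("diagnose: multivariate PSRF %.4f",
                                      attr(diag, "mpsrf")))

  log_lines <- c(log_lines, sprintf("wall clock: %.1f s",
                                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log_lines, path("run_log.txt"))

  invisible(list(graph = graph, sim = sim, kmodes = km, map = map,
                 fit_full = fit_full, fit_null = fit_null,
                 dic = dic, morans = mor, diagnostics = diag, out = out))
}
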