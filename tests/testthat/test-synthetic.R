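test_that("emit_responses reproduces the template at zero noise", {
  tpl <- default_templates()
  for (cat in 1:5) {
    out <- emit_responses(cat, epsilon = 0, n = 3)
    for (i in 1:3) expect_identical(matching_distance(out[i, ], tpl[cat, ]), 0L)
  }
  expect_error(emit_responses(1, epsilon = 1.2), "\\[0, 1\\]")
  expect_error(emit_responses(6, epsilon = 0), "template")
})

test_that("emit_responses flip noise has Binomial(10, eps) matching distance", {
  set.seed(11)
  tpl <- default_templates()
  out <- emit_responses(2, epsilon = 0.2, n = 10000)
  d <- sapply(seq_len(nrow(out)), function(i) matching_distance(out[i, ], tpl[2, ]))
  expect_lt(abs(mean(d) - 2), 0.08)   # 10 * 0.2, Monte-Carlo tolerance
})

test_that("the autonomous-category template splits decision items", {
  tpl <- default_templates()
  expect_identical(unname(unlist(tpl[4, c("d_visit", "d_purchase", "d_health")])),
                   rep("self", 3))
  expect_identical(tpl[4, "d_spend"], "partner")
})

test_that("simulation is reproducible bit-for-bit under a fixed seed", {
  g <- build_region_lattice(3, 3)
  a <- simulate_survey(g, psus_per_region = 3, respondents_per_psu = c(15, 20),
                       seed = 123)
  b <- simulate_survey(g, psus_per_region = 3, respondents_per_psu = c(15, 20),
                       seed = 123)
  expect_identical(a$data, b$data)
  expect_identical(a$truth$s, b$truth$s)
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("PSU sizes honour the configured range and jitter honours the caps", {
  sim <- small_sim(seed = 21, resp = c(15, 100))
  counts <- table(sim$data$psu)
  expect_true(all(counts >= 15 & counts <= 100))

  pt <- sim$truth$psu_table
  dist_km <- geosphere::distHaversine(
    cbind(pt$base_lon, pt$base_lat), cbind(pt$lon, pt$lat)) / 1000
  expect_true(all(dist_km[pt$urban == 1] <= 2 + 1e-6))
  expect_true(all(dist_km[pt$urban == 0] <= 5 + 1e-6))
})

test_that("a fully null ground truth yields equal category shares", {
  g <- build_region_lattice(4, 4)
  tr <- ground_truth(beta = matrix(0, 8, 2),
                     age_fn = list(function(a) 0 * a, function(a) 0 * a),
                     psu_sd = 0, region_sd = 1e-12, epsilon = 0,
                     s = matrix(0, 16, 2))
  sim <- simulate_survey(g, tr, psus_per_region = 8,
                         respondents_per_psu = c(40, 60), seed = 31)
  shares <- as.numeric(table(sim$truth$labels)) / length(sim$truth$labels)
  expect_true(all(abs(shares - 1 / 3) < 0.03))
})

test_that("category shares respond monotonically to the generating intercept", {
  g <- build_region_lattice(3, 3)
  base <- matrix(0, 8, 2)
  share1 <- function(b0) {
    beta <- base; beta[1, 1] <- b0
    tr <- ground_truth(beta = beta,
                       age_fn = list(function(a) 0 * a, function(a) 0 * a),
                       psu_sd = 0, region_sd = 1e-12, epsilon = 0,
                       s = matrix(0, 9, 2))
    sim <- simulate_survey(g, tr, psus_per_region = 5,
                           respondents_per_psu = c(30, 40), seed = 77)
    mean(sim$truth$labels == 1)
  }
  expect_lt(share1(-1), share1(0))
  expect_lt(share1(0), share1(1))
})

test_that("noise-free data is recovered exactly by the clustering stage", {
  g <- build_region_lattice(3, 3)
  tr <- ground_truth(epsilon = 0)
  sim <- simulate_survey(g, tr, psus_per_region = 3,
                         respondents_per_psu = c(15, 20), seed = 5)
  km <- kmodes(sim$data)
  expect_identical(km$cluster, sim$truth$labels)
})

test_that("minor categories appear only when requested", {
  sim0 <- small_sim(seed = 9)
  expect_true(all(sim0$truth$labels %in% 1:3))
  sim5 <- small_sim(seed = 9, include_minor_categories = TRUE)
  expect_true(any(sim5$truth$labels %in% 4:5))
})

test_that("survey and ground-truth files round-trip", {
  sim <- small_sim(seed = 13, rows = 2, cols = 2, psus = 2, resp = c(15, 18))
  fs <- tempfile(fileext = ".csv"); ft <- tempfile(fileext = ".json")
  on.exit(unlink(c(fs, ft)))
  write_survey(sim$data, fs)
  back <- read_survey(fs)
  expect_equal(back$age, sim$data$age)
  expect_identical(back$region, sim$data$region)
  expect_identical(back$v_burns, sim$data$v_burns)

  write_ground_truth(sim$truth, ft)
  tr <- read_ground_truth(ft)
  expect_equal(tr$beta, unname(sim$truth$beta))
  expect_equal(as.vector(tr$s), as.vector(sim$truth$s), tolerance = 1e-12)
  expect_identical(tr$labels, sim$truth$labels)
  expect_equal(tr$age_fn[[1]](20), sim$truth$age_fn[[1]](20), tolerance = 1e-12)
})
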