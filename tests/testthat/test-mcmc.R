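test_that("Polya-Gamma draws match the PG(1, z) moments", {
  set.seed(31)
  # E[PG(1,z)] = tanh(z/2)/(2z); Var[PG(1,0)] = 1/24
  for (z in c(0.5, 2, 6)) {
    d <- starmnl:::.rpg_vec(rep(z, 50000))
    expect_lt(abs(mean(d) - tanh(z / 2) / (2 * z)), 3 * sd(d) / sqrt(50000) + 1e-4)
  }
  d0 <- starmnl:::.rpg_vec(rep(0, 50000))
  expect_lt(abs(mean(d0) - 0.25), 0.002)
  expect_lt(abs(var(d0) - 1 / 24), 0.002)
})

test_that("retained draw count equals (iterations - burnin)/thinning per chain", {
  sim <- small_sim(seed = 41, rows = 2, cols = 2, psus = 2, resp = c(15, 18))
  dat <- sim$data; dat$category <- sim$truth$labels
  fit <- star_mnl(category ~ urban + s(age) + re(psu) + mrf(region),
                  data = dat, graph = sim$graph,
                  iterations = 1200, burnin = 200, thin = 10,
                  chains = 2, seed = 2)
  expect_identical(dim(fit$chains[[1]]$beta)[3], 100L)
  expect_identical(dim(fit$chains[[2]]$beta)[3], 100L)
  expect_identical(length(fit$chains[[1]]$deviance), 100L)
})

test_that("every retained region-effect draw satisfies the sum-to-zero constraint", {
  sim <- small_sim(seed = 43, rows = 2, cols = 3, psus = 3, resp = c(15, 20))
  dat <- sim$data; dat$category <- sim$truth$labels
  fit <- star_mnl(category ~ urban + educ + income + s(age) + re(psu) + mrf(region),
                  data = dat, graph = sim$graph,
                  iterations = 600, burnin = 100, thin = 5, seed = 3)
  s <- fit$chains[[1]]$s    # J x 2 x draws
  sums <- apply(s, 3, colSums)
  expect_lt(max(abs(sums)), 1e-8)
  tau <- fit$chains[[1]]$tau2
  expect_true(all(tau > 0))
})

test_that("the null model is the spatial model without the structured effect", {
  sim <- small_sim(seed = 47, rows = 2, cols = 2, psus = 3, resp = c(15, 20))
  dat <- sim$data; dat$category <- sim$truth$labels
  fit <- star_mnl(category ~ urban + s(age) + re(psu),
                  data = dat, iterations = 400, burnin = 100, thin = 5, seed = 4)
  expect_identical(fit$model, "null")
  expect_false(fit$has$spatial)
  expect_identical(dim(fit$chains[[1]]$s), c(0L, 2L, 0L))
  expect_error(region_effects(fit), "no structured region effect")
})

test_that("posterior means match a deterministic quadrature oracle (n = 40)", {
  set.seed(99)
  y <- sample(1:3, 40, replace = TRUE, prob = c(0.45, 0.3, 0.25))
  fit <- star_mnl(category ~ 1, data = data.frame(category = y),
                  iterations = 42000, burnin = 2000, thin = 5, seed = 11)
  bd <- starmnl:::pooled_draws(fit, "beta")
  mc_mean <- colMeans(bd)
  mcse <- apply(bd, 2, function(x) sqrt(spectrum0(x) / length(x)))
  oracle <- quadrature_posterior_means(y)
  expect_true(all(abs(mc_mean - oracle) < 3 * mcse))
})

test_that("posterior summaries use type-7 quantiles and monotone odds ratios", {
  draws <- matrix(1:100, ncol = 1, dimnames = list(NULL, "a"))
  sm <- summarize_posterior(draws)
  expect_equal(sm$median, 50.5)
  expect_equal(sm$q2.5, 3.475)
  expect_equal(sm$q97.5, 97.525)   # 1 + 0.975 * 99

  sm2 <- summarize_posterior(draws / 50, exp_transform = TRUE)
  expect_equal(sm2$or_q2.5, exp(sm2$q2.5))
  expect_equal(sm2$or_q97.5, exp(sm2$q97.5))
  expect_true(sm2$or_q2.5 < sm2$or_median && sm2$or_median < sm2$or_q97.5)

  zero <- matrix(0, 50, 1, dimnames = list(NULL, "b"))
  smz <- summarize_posterior(zero, exp_transform = TRUE)
  expect_identical(smz$or_median, 1)
  expect_identical(smz$or_q97.5 - smz$or_q2.5, 0)
})

test_that("DIC components obey the defining identities", {
  expect_identical(unname(compute_dic(rep(100, 10), 100)["pD"]), 0)
  expect_identical(unname(compute_dic(rep(100, 10), 100)["DIC"]), 100)
  dic <- compute_dic(c(90, 110), 94)
  expect_equal(unname(dic["Dbar"]), 100)
  expect_equal(unname(dic["pD"]), 6)
  expect_equal(unname(dic["DIC"]), 106)
  expect_equal(unname(dic["DIC"]), unname(dic["Dhat"] + 2 * dic["pD"]))
  expect_error(compute_dic(numeric(0), 1), "empty")
})

test_that("model accessors return coherent shapes", {
  sim <- small_sim(seed = 53, rows = 2, cols = 2, psus = 3, resp = c(15, 20))
  dat <- sim$data; dat$category <- sim$truth$labels
  fit <- star_mnl(category ~ urban + educ + income + s(age) + re(psu) + mrf(region),
                  data = dat, graph = sim$graph,
                  iterations = 600, burnin = 100, thin = 5, seed = 5)
  expect_identical(dim(coef(fit)), c(8L, 2L))
  P <- fitted(fit)
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  R <- residuals(fit)
  expect_equal(dim(R), dim(P))
  expect_true(all(abs(rowSums(R)) < 1e-12))
  re <- region_effects(fit)
  expect_identical(nrow(re), 2L * length(sim$graph$region_ids))
  ae <- age_effect(fit, grid = c(20, 30, 40))
  expect_identical(nrow(ae$k1), 3L)
  expect_output(print(fit), "DIC")
  expect_output(print(summary(fit)), "odds ratios")
})
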