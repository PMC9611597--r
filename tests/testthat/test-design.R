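toy_respondents <- function() {
  data.frame(
    resp_id = 1:3,
    region = c("r1", "r1", "r2"), psu = c(1L, 1L, 2L),
    lon = 0, lat = 0,
    age = c(20L, 35L, 49L),
    urban = c(0L, 1L, 1L),
    educ = c("none", "secondary+", "primary"),
    income = c("poorest", "richest", "middle"),
    stringsAsFactors = FALSE)
}

test_that("covariate coding uses references rural / none / poorest", {
  d <- toy_respondents()
  d$category <- c(1L, 2L, 3L)
  des <- build_design(d)
  expect_identical(unname(des$X[1, ]), c(1, 0, 0, 0, 0, 0, 0, 0))
  expect_identical(unname(des$X[2, ]), c(1, 1, 0, 1, 0, 0, 0, 1))
  expect_identical(unname(des$X[3, ]), c(1, 1, 1, 0, 0, 1, 0, 0))
  expect_true(all(rowSums(des$Y) == 1))

  d$educ[2] <- "college"
  expect_error(build_design(d), "unknown educ level 'college' for respondent 2")
})

test_that("respondents outside categories 1-3 are excluded from the design", {
  d <- toy_respondents()
  d$category <- c(1L, 4L, 3L)
  des <- build_design(d)
  expect_identical(nrow(des$X), 2L)
  expect_identical(des$keep, c(1L, 3L))
})

test_that("B-spline basis has M = knots + degree columns and partitions unity", {
  ages <- 15:49
  B <- bspline_basis(ages, knots = 20, degree = 3)
  expect_identical(ncol(B), 23L)
  expect_true(all(abs(rowSums(B) - 1) < 1e-10))
  expect_true(all(B >= 0))
  # local support: at most degree + 1 nonzero basis functions per row
  expect_true(all(rowSums(B > 0) <= 4))
  expect_warning(bspline_basis(c(10, 30), span = c(15, 49)), "clamped")
})

test_that("RW2 penalty has rank M - 2 with linear trends in its null space", {
  K <- starmnl:::rw2_penalty(23)
  expect_identical(qr(K)$rank, 21L)
  m <- seq_len(23)
  expect_lt(max(abs(K %*% (2 + 0.5 * m))), 1e-10)
})

test_that("multinomial probabilities match the logit link and its limits", {
  expect_equal(unname(multinomial_probs(0, 0)[1, ]), rep(1 / 3, 3))
  expect_equal(unname(multinomial_probs(log(2), 0)[1, ]), c(0.5, 0.25, 0.25))
  expect_equal(unname(multinomial_probs(-500, 0)[1, ]), c(0, 0.5, 0.5))
  # overflow safety and exact normalisation
  set.seed(12)
  eta1 <- c(rnorm(100, 0, 3), 700, -700)
  eta2 <- c(rnorm(100, 0, 3), -700, 700)
  P <- multinomial_probs(eta1, eta2)
  expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  expect_true(all(P >= 0))
})

test_that("log-likelihood is additive and matches brute-force substitution", {
  d <- toy_respondents()
  d$category <- c(3L, 3L, 3L)
  des <- build_design(d[1, ])
  expect_equal(star_loglik(des, beta = matrix(0, 8, 2)), log(1 / 3))

  set.seed(23)
  n <- 5
  d5 <- data.frame(resp_id = 1:n, region = "r1", psu = 1L, lon = 0, lat = 0,
                   age = sample(15:49, n, TRUE),
                   urban = rbinom(n, 1, 0.5),
                   educ = sample(c("none", "primary", "secondary+"), n, TRUE),
                   income = sample(c("poorest", "poorer", "middle", "richer",
                                     "richest"), n, TRUE),
                   category = sample(1:3, n, TRUE))
  des5 <- build_design(d5)
  beta <- matrix(rnorm(16), 8, 2)
  eta1 <- drop(des5$X %*% beta[, 1]); eta2 <- drop(des5$X %*% beta[, 2])
  expect_equal(star_loglik(des5, beta),
               brute_force_loglik(des5$y, eta1, eta2), tolerance = 1e-12)

  d10 <- rbind(d5, d5); d10$resp_id <- 1:(2 * n)
  expect_equal(star_loglik(build_design(d10), beta),
               2 * star_loglik(des5, beta), tolerance = 1e-12)
})
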