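make_psu_data <- function(labels, psu) {
  data.frame(psu = psu, region = "r1", lon = psu, lat = 0, labels = labels)
}

test_that("PSU proportions follow the category-1-3 exclusion rule", {
  d <- make_psu_data(c(rep(1, 5), rep(2, 3), rep(3, 2)), rep(1L, 10))
  out <- psu_proportions(d$labels, d)
  expect_equal(unlist(out[1, c("p1", "p2", "p3")], use.names = FALSE),
               c(0.5, 0.3, 0.2))

  d2 <- make_psu_data(rep(1, 4), rep(1L, 4))
  expect_equal(unlist(psu_proportions(d2$labels, d2)[1, c("p1", "p2", "p3")],
                      use.names = FALSE), c(1, 0, 0))

  # categories 4/5 excluded from numerator and denominator
  d3 <- make_psu_data(c(1, 1, 4, 2), rep(1L, 4))
  out3 <- psu_proportions(d3$labels, d3)
  expect_identical(out3$n1 + out3$n2 + out3$n3, 3L)
  expect_equal(unlist(out3[1, c("p1", "p2", "p3")], use.names = FALSE),
               c(2 / 3, 1 / 3, 0))

  # PSU entirely outside 1-3 is flagged
  d4 <- make_psu_data(c(1, 2, 4, 4), c(1L, 1L, 2L, 2L))
  out4 <- psu_proportions(d4$labels, d4)
  expect_identical(out4$empty, c(FALSE, TRUE))
  expect_true(is.na(out4$p1[2]))
})

test_that("colour blending maps pure and mixed proportions as declared", {
  expect_identical(blend_rgb(1, 0, 0), cbind(r = 0L, g = 0L, b = 255L))
  expect_identical(blend_rgb(0, 1, 0), cbind(r = 255L, g = 0L, b = 0L))
  expect_identical(blend_rgb(0, 0, 1), cbind(r = 0L, g = 255L, b = 0L))
  expect_identical(blend_rgb(1/3, 1/3, 1/3), cbind(r = 85L, g = 85L, b = 85L))
  expect_error(blend_rgb(0.5, 0.2, 0.2), "sum to 1")
  # linear in each proportion
  expect_identical(blend_rgb(0.2, 0.8, 0)[, "r"], c(r = as.integer(round(255 * 0.8))))
})

test_that("Moran's I equals -1 on a checkerboard and is positive on a gradient", {
  g <- build_region_lattice(4, 4)
  W <- region_weights(g)
  coords <- attr(g, "coords")
  chk <- ifelse((coords[, "row"] + coords[, "col"]) %% 2 == 0, 1, -1)
  expect_equal(morans_i(chk, W), -1, tolerance = 1e-12)

  grad <- coords[, "row"] + coords[, "col"]
  expect_gt(morans_i(grad, W), 0)
})

test_that("Moran's I has permutation-null mean -1/(n-1) and affine invariance", {
  g <- build_region_lattice(4, 4)
  W <- region_weights(g)
  set.seed(4)
  x <- rnorm(16)
  perm_I <- replicate(3000, morans_i(sample(x), W))
  expect_lt(abs(mean(perm_I) - (-1 / 15)), 0.012)
  expect_equal(morans_i(3 * x - 10, W), morans_i(x, W), tolerance = 1e-12)
})

test_that("Moran's I matches an independent implementation and guards inputs", {
  g <- build_region_lattice(3, 5)
  W <- region_weights(g)
  set.seed(6)
  x <- rnorm(15)
  Wr <- W / rowSums(W)
  expect_equal(morans_i(x, W), ape::Moran.I(x, Wr)$observed, tolerance = 1e-10)

  expect_error(morans_i(rep(1, 15), W), "constant")
  Wneg <- W; Wneg[1, 2] <- -1
  expect_error(morans_i(x, Wneg), "nonnegative")
  Wd <- W; diag(Wd) <- 1
  expect_error(morans_i(x, Wd), "zero diagonal")
  Wempty <- W; Wempty[1, ] <- 0; Wempty[, 1] <- 0
  expect_warning(I <- morans_i(x, Wempty), "dropped")
  expect_true(is.finite(I))
})

test_that("knn weights are symmetric 0/1 with zero diagonal", {
  set.seed(2)
  lon <- runif(30, -10, 0); lat <- runif(30, 5, 12)
  W <- knn_weights(lon, lat, k = 5)
  expect_identical(W, t(W))
  expect_true(all(W %in% c(0, 1)))
  expect_true(all(diag(W) == 0))
  expect_true(all(rowSums(W) >= 5))
})
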