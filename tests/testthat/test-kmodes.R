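test_that("matching distance: identity, symmetry, and the primed-mode distances", {
  im <- default_initial_modes()
  expect_identical(matching_distance(im[1, ], im[1, ]), 0L)
  expect_identical(matching_distance(im[1, ], im[2, ]), 10L)  # every item differs
  expect_identical(matching_distance(im[1, ], im[3, ]), 4L)   # only decision items
  expect_identical(matching_distance(im[2, ], im[4, ]), 10L)
  expect_identical(matching_distance(im[4, ], im[1, ]),
                   matching_distance(im[1, ], im[4, ]))
})

test_that("primed initial modes are the five declared patterns, pairwise distinct", {
  im <- default_initial_modes()
  expect_identical(nrow(im), 5L)
  expect_identical(unname(unlist(im[3, ])),
                   c(rep("no", 5), rep("partner", 4), "yes"))
  expect_identical(unname(unlist(im[5, ])),
                   c(rep("dont_know", 5), rep("other", 4), "dont_know"))
  for (i in 1:4) for (j in (i + 1):5)
    expect_gt(matching_distance(im[i, ], im[j, ]), 0)
})

test_that("update_mode takes item-wise pluralities with the declared tie-break", {
  im <- default_initial_modes()
  expect_identical(unname(unlist(update_mode(im[2, ]))), unname(unlist(im[2, ])))

  three <- im[c(1, 1, 1), ]
  three$v_burns <- c("no", "no", "yes")
  expect_identical(update_mode(three)$v_burns, "no")

  two <- im[c(1, 1), ]
  two$refuse_sex <- c("yes", "no")   # 1-1 tie -> lowest declared level ("yes")
  expect_identical(update_mode(two)$refuse_sex, "yes")
  two$d_spend <- c("partner", "self")  # tie -> "self" comes first
  expect_identical(update_mode(two)$d_spend, "self")

  expect_error(update_mode(im[integer(0), ]), "empty cluster")
})

test_that("the five modes themselves form a zero-cost fixed point", {
  im <- default_initial_modes()
  fit <- kmodes(im)
  expect_identical(fit$cluster, 1:5)
  expect_identical(fit$cost, 0L)
  expect_true(fit$converged)
  expect_identical(unname(unlist(fit$modes)), unname(unlist(im)))
})

test_that("noise-free template data leaves the primed modes unchanged", {
  pd <- planted_data(n_per_cat = 40, epsilon = 0)
  fit <- kmodes(pd$data)
  expect_identical(unname(unlist(fit$modes[1:3, ])),
                   unname(unlist(default_initial_modes()[1:3, ])))
  expect_identical(fit$cluster, pd$labels)
  expect_identical(fit$cost, 0L)
})

test_that("cost is non-increasing and the batch solution is order-independent", {
  set.seed(3)
  pd <- planted_data(n_per_cat = 100, epsilon = 0.15)
  fit <- kmodes(pd$data)
  expect_true(all(diff(fit$cost_history) <= 0))
  expect_true(fit$converged)

  perm <- sample(nrow(pd$data))
  fit2 <- kmodes(pd$data[perm, ])
  expect_identical(fit2$cost, fit$cost)
  expect_identical(fit2$cluster, fit$cluster[perm])
})

test_that("converged assignment is locally optimal (brute-force cross-check)", {
  set.seed(8)
  pd <- planted_data(n_per_cat = 4, epsilon = 0.3)   # n = 12
  init <- default_initial_modes()[c(1, 2), ]
  fit <- kmodes(pd$data, modes = init)
  D <- starmnl:::distance_to_modes(pd$data, fit$modes)
  # no single-point relabelling lowers the cost given the final modes
  expect_true(all(D[cbind(seq_len(12), fit$cluster)] == apply(D, 1, min)))

  # enumerate all 2^12 assignments; converged cost is bounded below by the
  # global optimum over (assignment, plurality-mode) pairs
  best <- Inf
  for (code in 0:(2^12 - 1)) {
    lab <- as.integer(intToBits(code)[1:12]) + 1L
    if (length(unique(lab)) < 2L) next
    cost <- 0L
    for (m in 1:2) {
      members <- pd$data[lab == m, , drop = FALSE]
      mode_m <- update_mode(members)
      cost <- cost + sum(starmnl:::distance_to_modes(members, mode_m))
    }
    if (cost < best) best <- cost
  }
  expect_gte(fit$cost, best)
})

test_that("clustering recovers planted labels under moderate flip noise", {
  set.seed(19)
  pd <- planted_data(n_per_cat = 500, epsilon = 0.05)
  fit <- kmodes(pd$data)
  ari <- helper_ari(fit$cluster, pd$labels)
  expect_gt(ari, 0.95)
  # cross-check the helper ARI against an independent implementation
  expect_equal(ari, mclust::adjustedRandIndex(fit$cluster, pd$labels),
               tolerance = 1e-12)
})

test_that("incomplete or inadmissible responses are rejected at input", {
  im <- default_initial_modes()
  bad <- im; bad$v_burns[1] <- NA
  expect_error(kmodes(bad), "missing values")
  bad2 <- im; bad2$d_visit[2] <- "unsure"
  expect_error(kmodes(bad2), "inadmissible")
  expect_error(kmodes(im[, -1]), "missing item columns")
})
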