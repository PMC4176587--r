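test_that("membership formula matches hand computation and brute force", {
  # equidistant gene: equal memberships
  u <- fcm_memberships(matrix(c(2, 2), 1), m = 2)
  expect_equal(unname(u), matrix(c(0.5, 0.5), 1))

  # m = 2, distances (1, 2): exponent 2/(m-1) = 2 -> (0.8, 0.2)
  u2 <- fcm_memberships(matrix(c(1, 2), 1), m = 2)
  expect_equal(unname(u2), matrix(c(0.8, 0.2), 1))

  withr::with_seed(11, {
    for (i in 1:20) {
      d <- matrix(runif(8 * 4, 0.05, 5), 8, 4)
      m <- runif(1, 1.1, 3)
      expect_equal(fcm_memberships(d, m), membership_bruteforce(d, m),
                   tolerance = 1e-12)
    }
  })

  # exact hit: membership 1 on the hit centroid
  u3 <- fcm_memberships(matrix(c(0, 3, 1), 1), m = 1.35)
  expect_equal(unname(u3), matrix(c(1, 0, 0), 1))
  expect_error(fcm_memberships(matrix(-1), m = 2), "non-negative")
  expect_error(fcm_memberships(matrix(1), m = 1), "> 1")
})

test_that("membership rows always sum to one", {
  x <- two_blobs()
  fit <- fcm_fit(x, centers = 3, m = 1.6, seed = 5)
  expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
  expect_true(all(fit$memberships >= 0 & fit$memberships <= 1))
})

test_that("two separated blobs give blob-mean centroids and crisp memberships", {
  x <- two_blobs(n = 50, sep = 10, sd = 0.2)
  for (seed in 1:3) {
    fit <- fcm_fit(x, centers = 2, m = 1.35, seed = seed)
    cent <- fit$centroids[order(fit$centroids[, 1]), ]
    expect_equal(unname(cent[1, ]), unname(colMeans(x[1:50, ])),
                 tolerance = 0.05)
    expect_equal(unname(cent[2, ]), unname(colMeans(x[51:100, ])),
                 tolerance = 0.05)
    expect_true(all(apply(fit$memberships, 1, max) > 0.99))
  }
})

test_that("objective trace is non-increasing and convergence is flagged", {
  withr::with_seed(2, {
    for (i in 1:5) {
      x <- matrix(rnorm(150 * 5), 150, 5,
                  dimnames = list(sprintf("g%d", 1:150), NULL))
      fit <- fcm_fit(x, centers = sample(3:6, 1),
                     m = sample(c(1.2, 1.35, 2), 1), seed = i)
      tr <- fit$objective_trace
      expect_true(all(diff(tr) <= 1e-8 * abs(tr[-length(tr)])))
    }
  })
})

test_that("fits are deterministic given the seed and equivariant to row order", {
  x <- two_blobs(seed = 3)
  f1 <- fcm_fit(x, centers = 2, seed = 9, tol = 1e-9, max_iter = 2000)
  f2 <- fcm_fit(x, centers = 2, seed = 9, tol = 1e-9, max_iter = 2000)
  expect_identical(f1$memberships, f2$memberships)

  perm <- withr::with_seed(1, sample(nrow(x)))
  f3 <- fcm_fit(x[perm, ], centers = 2, seed = 9, warm_start = FALSE,
                tol = 1e-9, max_iter = 2000)
  # same stationary point up to cluster relabeling: compare sorted centroids
  o1 <- order(f1$centroids[, 1])
  o3 <- order(f3$centroids[, 1])
  expect_equal(unname(f1$centroids[o1, ]), unname(f3$centroids[o3, ]),
               tolerance = 1e-4)
})

test_that("fcm fixed point agrees with the e1071 reference implementation", {
  skip_if_not_installed("e1071")
  x <- two_blobs(n = 40, sep = 6, sd = 0.4, seed = 8)
  fit <- fcm_fit(x, centers = 2, m = 1.5, seed = 1, tol = 1e-10,
                 max_iter = 1000)
  ref <- e1071::cmeans(x, centers = fit$centroids, m = 1.5,
                       iter.max = 1000, method = "cmeans")
  o <- order(ref$centers[, 1])
  expect_equal(unname(ref$centers[o, ]),
               unname(fit$centroids[order(fit$centroids[, 1]), ]),
               tolerance = 1e-4)
  expect_equal(unname(ref$membership[, o]),
               unname(fit$memberships[, order(fit$centroids[, 1])]),
               tolerance = 1e-4)
})

test_that("large m flattens memberships toward 1/c", {
  x <- two_blobs(n = 30, sep = 3, sd = 0.5, seed = 2)
  fit <- fcm_fit(x, centers = 3, m = 25, seed = 1)
  # flat landscape: the typical membership approaches 1/c and almost no gene
  # clears the 0.5 anchor (genes sitting on a centroid are the exception)
  expect_lt(median(abs(fit$memberships - 1 / 3)), 0.05)
  expect_lt(glance(fit)$frac_high_membership, 0.05)
})

test_that("input validation rejects degenerate clustering problems", {
  x <- two_blobs(n = 3)
  expect_error(fcm_fit(x, centers = 1), ">= 2")
  expect_error(fcm_fit(x, centers = 2, m = 1), "> 1")
  expect_error(fcm_fit(x[1:2, ], centers = 2), "more genes")
  bad <- x
  bad[1, 1] <- NA
  expect_error(fcm_fit(bad, centers = 2), "finite")
})

test_that("hard assignment respects the membership threshold", {
  x <- two_blobs(n = 20, sep = 10, sd = 0.1)
  fit <- fcm_fit(x, centers = 2, seed = 1)
  ha <- hard_assignments(fit)
  expect_true(all(!is.na(ha$cluster)))
  expect_equal(dplyr::n_distinct(ha$cluster), 2L)
  ha_strict <- hard_assignments(fit, threshold = 1.01)
  expect_true(all(is.na(ha_strict$cluster)))
})

test_that("adjusted Rand index matches the mclust reference and handles NA", {
  skip_if_not_installed("mclust")
  withr::with_seed(6, {
    for (i in 1:10) {
      a <- sample(letters[1:4], 60, replace = TRUE)
      b <- sample(1:3, 60, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
  })
  expect_equal(adjusted_rand_index(c("a", "a", "b"), c("x", "x", "y")), 1)
  a <- c("a", "a", "b", NA)
  b <- c("x", "x", "y", "z")
  expect_equal(adjusted_rand_index(a, b), 1)
})
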