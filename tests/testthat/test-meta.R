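test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  q <- quantile_normalize(m)
  expect_equal(unname(q[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, "b"]), c(2.5, 3.5, 4.5))

  withr::with_seed(2, {
    x <- matrix(rnorm(200 * 5, mean = rep(1:5, each = 200)), 200, 5)
    q1 <- quantile_normalize(x)
    # identical sorted columns
    ref <- sort(q1[, 1])
    for (j in 2:5) expect_equal(sort(q1[, j]), ref, tolerance = 1e-12)
    # idempotence
    expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  })

  # identical columns are a fixed point
  same <- cbind(x = c(3, 1, 2), y = c(3, 1, 2))
  expect_equal(quantile_normalize(same), same)

  expect_warning(quantile_normalize(matrix(1:3, 3, 1)), "no-op")
  expect_error(quantile_normalize(cbind(c(1, NA), c(1, 2))), "complete")
})

test_that("range scaling hits the endpoints, preserves signs and ranks", {
  s <- scale_to_range(c(-2, 0, 2))
  expect_equal(s, c(-4.03, 0, 4.07))

  # already spanning the target: fixed point
  expect_equal(scale_to_range(c(-4.03, 1, 4.07)), c(-4.03, 1, 4.07))

  withr::with_seed(4, {
    for (i in 1:50) {
      x <- rnorm(sample(5:80, 1), sd = runif(1, 0.1, 6))
      s <- scale_to_range(x)
      expect_true(all(s >= -4.03 - 1e-12 & s <= 4.07 + 1e-12))
      expect_true(all(sign(s) == sign(x)))
      expect_true(all(diff(s[order(x)]) >= -1e-12))
    }
  })

  expect_warning(z <- scale_to_range(c(0, 0)), "nonzero")
  expect_equal(z, c(0, 0))
  expect_error(scale_to_range(1:3, range = c(1, 4)), "lo < 0 < hi")
})

test_that("recurrence selection counts significance flags across studies", {
  studies <- tibble::tibble(
    study = rep(c("s1", "s2", "s3"), each = 3),
    gene = rep(c("g1", "g2", "g3"), 3),
    significant = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  sel <- select_recurrent(studies)
  expect_equal(sel$n_significant[sel$gene == "g1"], 2L)
  expect_true(sel$selected[sel$gene == "g1"])
  expect_false(sel$selected[sel$gene == "g2"])
  # vacuous threshold: union of all significant sets
  sel1 <- select_recurrent(studies, min_count = 1)
  expect_setequal(sel1$gene[sel1$selected], c("g1", "g2"))
  expect_error(select_recurrent(studies[studies$study == "s1", ]),
               "two studies")
})

test_that("complete linkage matches brute-force agglomeration", {
  # 1-D worked case {0, 1, 10}: merge at 1, then at 10
  hc <- hclust_complete(matrix(c(0, 1, 10), 3, 1,
                               dimnames = list(c("a", "b", "c"), NULL)))
  expect_equal(hc$height, c(1, 10))

  # duplicated item merges at height 0 first
  hc0 <- hclust_complete(matrix(c(0, 0, 5), 3, 1))
  expect_equal(hc0$height[1], 0)

  withr::with_seed(9, {
    for (i in 1:40) {
      n <- sample(3:8, 1)
      x <- matrix(rnorm(n * 2), n, 2)
      hc <- hclust_complete(x)
      expect_equal(sort(hc$height), sort(linkage_bruteforce(dist(x))),
                   tolerance = 1e-9)
      # ultrametric property: non-decreasing merge heights
      expect_true(all(diff(hc$height) >= -1e-12))
      # label permutation leaves the height profile unchanged
      perm <- sample(n)
      hc_p <- hclust_complete(x[perm, , drop = FALSE])
      expect_equal(sort(hc_p$height), sort(hc$height), tolerance = 1e-9)
    }
  })
  expect_error(hclust_complete(matrix(1, 1, 2)), "two items")
})

test_that("subtree detection and newick export work on a known tree", {
  x <- matrix(c(0, 0.5, 10, 10.6, 30), 5, 1,
              dimnames = list(sprintf("i%d", 1:5), NULL))
  hc <- hclust_complete(x)
  expect_true(leaves_form_subtree(hc, c("i1", "i2")))
  expect_true(leaves_form_subtree(hc, c("i3", "i4")))
  expect_false(leaves_form_subtree(hc, c("i2", "i3")))
  expect_true(leaves_form_subtree(hc, "i5"))
  expect_true(leaves_form_subtree(hc, sprintf("i%d", 1:5)))

  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "^\\(")
  expect_true(all(vapply(sprintf("i%d", 1:5), grepl, logical(1), nwk)))
})

test_that("zero-noise planted module is selected exactly", {
  ms <- simulate_multistudy(
    n_studies = 6, n_genes = 80,
    modules = list(list(genes = 1:15, studies = 1:3, effect = 3)),
    noise_sd = 0, sig_threshold = 1, seed = 5
  )
  counts <- select_recurrent(ms$studies)
  expect_setequal(counts$gene[counts$selected], ms$truth[[1]]$genes)
})

test_that("affected studies cluster together and duplicates sit adjacent", {
  ms <- simulate_multistudy(
    n_studies = 6, n_genes = 200,
    modules = list(list(genes = 1:25, studies = 1:3, effect = 3)),
    noise_sd = 0.2, sig_threshold = 1, seed = 5
  )
  im <- suppressMessages(build_heatmap_matrix(ms$studies))
  expect_setequal(rownames(im$values), ms$truth[[1]]$genes)
  expect_true(leaves_form_subtree(im$col_hclust, sprintf("study%02d", 1:3)))
  expect_true(all(im$values >= -4.03 - 1e-12 & im$values <= 4.07 + 1e-12))

  # an exactly duplicated study column sits adjacent in the leaf order
  dup <- dplyr::bind_rows(
    ms$studies,
    dplyr::mutate(dplyr::filter(ms$studies, study == "study01"),
                  study = "study_copy")
  )
  im2 <- suppressMessages(build_heatmap_matrix(dup))
  ord <- im2$col_order
  expect_equal(abs(which(ord == "study01") - which(ord == "study_copy")), 1)
})

test_that("integrated matrix tidies in display order for plotting", {
  ms <- simulate_multistudy(
    n_studies = 4, n_genes = 40,
    modules = list(list(genes = 1:10, studies = 1:2, effect = 2.5)),
    noise_sd = 0.1, sig_threshold = 1, seed = 6
  )
  im <- suppressMessages(build_heatmap_matrix(ms$studies))
  td <- tidy(im)
  expect_setequal(names(td), c("gene", "study", "log2_ratio"))
  expect_identical(levels(td$study), im$col_order)
  expect_identical(levels(td$gene), im$row_order)
  p <- autoplot(im)
  expect_s3_class(p, "ggplot")
})
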