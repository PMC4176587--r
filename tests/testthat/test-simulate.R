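test_that("simulator layout, determinism and zero-noise exactness", {
  cfg <- small_config(seed = 7)
  sim1 <- simulate_timecourse(cfg)
  sim2 <- simulate_timecourse(cfg)
  expect_identical(sim1$expression, sim2$expression)

  m <- expression_matrix(sim1$expression)
  expect_equal(dim(m), c(120L, 2L * 4L * 3L))
  expect_equal(nrow(sim1$truth), 120L)
  expect_setequal(sim1$truth$archetype, c("up", "down", "pulse"))

  noiseless <- simulation_config(
    archetypes = list(archetype("a", c(1, 2, 3), 5, noise_sd = 0)),
    times = c(0, 1, 2), n_replicates = 2, seed = 1
  )
  sim0 <- simulate_timecourse(noiseless)
  m0 <- expression_matrix(sim0$expression)
  for (t in c(0, 1, 2)) {
    cols <- grepl(sprintf("_%gh_", t), colnames(m0))
    expect_true(all(m0[, cols] == t + 1))
  }
})

test_that("strain effect is applied to the producer strain only", {
  cfg <- simulation_config(
    archetypes = list(archetype("a", c(5, 5), 4, noise_sd = 0,
                                strain_effect = c(1, 2))),
    times = c(0, 1), n_replicates = 1, seed = 3
  )
  m <- expression_matrix(simulate_timecourse(cfg)$expression)
  expect_true(all(m[, "producer_0h_r1"] == 6))
  expect_true(all(m[, "producer_1h_r1"] == 7))
  expect_true(all(m[, "control_0h_r1"] == 5))
  expect_true(all(m[, "control_1h_r1"] == 5))
})

test_that("archetype column means match planted means at large n", {
  sim <- simulate_timecourse(study_config(seed = 11))
  m <- expression_matrix(sim$expression)
  noise_sd <- 0.2
  tol <- 3 * noise_sd / sqrt(200 * 3)
  arch <- sim$config$archetypes[[1]]
  genes <- sim$truth$gene[sim$truth$archetype == arch$name]
  for (ti in seq_along(sim$config$times)) {
    cols <- grepl(sprintf("^control_%gh_", sim$config$times[ti]), colnames(m))
    expect_lt(abs(mean(m[genes, cols]) - arch$base_profile[ti]), tol)
  }
})

test_that("configuration validation rejects degenerate designs", {
  expect_error(simulation_config(times = c(0)), "two time points")
  expect_error(simulation_config(n_replicates = 0), "n_replicates")
  expect_error(simulation_config(archetypes = list()), "empty")
  expect_error(
    simulation_config(archetypes = list(archetype("a", c(1, 2), 5))),
    "per time point"
  )
  expect_error(archetype("a", c(1, 2), n_genes = 0), "n_genes")
  expect_error(archetype("a", c(1, 2), 5, noise_sd = -1), "noise_sd")
})

test_that("term map plants members from the source archetype", {
  cfg <- small_config(seed = 5)
  sim <- simulate_timecourse(cfg)
  tc <- tibble::tibble(
    term = c("T_pure", "T_bg"),
    archetype = c("up", NA),
    n_in_term = c(30L, 0L),
    n_background = c(0L, 20L)
  )
  terms <- simulate_term_map(cfg, sim$truth, tc)
  up_genes <- sim$truth$gene[sim$truth$archetype == "up"]
  expect_length(terms$T_pure, 30L)
  expect_true(all(terms$T_pure %in% up_genes))
  expect_length(terms$T_bg, 20L)

  # disjoint source archetypes with no shared background
  tc2 <- tibble::tibble(
    term = c("A", "B"), archetype = c("up", "down"),
    n_in_term = c(20L, 20L), n_background = c(0L, 0L)
  )
  t2 <- simulate_term_map(cfg, sim$truth, tc2)
  expect_length(intersect(t2$A, t2$B), 0L)

  bad <- tibble::tibble(term = "X", archetype = "up",
                        n_in_term = 1000L, n_background = 0L)
  expect_error(simulate_term_map(cfg, sim$truth, bad), "exceeds")
})

test_that("multi-study simulator plants effects and flags deterministically", {
  mod <- list(list(genes = 1:10, studies = 1:2, effect = 3))
  ms <- simulate_multistudy(n_studies = 4, n_genes = 50, modules = mod,
                            noise_sd = 0, sig_threshold = 1, seed = 2)
  ms2 <- simulate_multistudy(n_studies = 4, n_genes = 50, modules = mod,
                             noise_sd = 0, sig_threshold = 1, seed = 2)
  expect_identical(ms$studies, ms2$studies)

  flags <- dplyr::summarise(dplyr::group_by(ms$studies, gene),
                            n = sum(significant), .groups = "drop")
  planted <- ms$truth[[1]]$genes
  expect_true(all(flags$n[flags$gene %in% planted] == 2L))
  expect_true(all(flags$n[!flags$gene %in% planted] == 0L))

  # near-zero noise with threshold 1: normal tail makes flags essentially
  # impossible without a planted effect
  null_ms <- simulate_multistudy(n_studies = 5, n_genes = 200, modules = list(),
                                 noise_sd = 0.1, sig_threshold = 1, seed = 9)
  expect_equal(sum(null_ms$studies$significant), 0L)

  conflicting <- list(
    list(genes = 1:5, studies = 1, effect = 2),
    list(genes = 3:8, studies = 1, effect = -2)
  )
  expect_error(
    simulate_multistudy(n_studies = 2, n_genes = 10, modules = conflicting),
    "conflicting"
  )
})

test_that("row permutation preserves row multisets and decorrelates rows", {
  x <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  p1 <- permute_matrix(x, seed = 4)
  p2 <- permute_matrix(x, seed = 4)
  expect_identical(p1, p2)
  expect_setequal(p1["a", ], c(1, 2, 3))
  expect_setequal(p1["b", ], c(4, 5, 6))

  # correlated rows become uncorrelated on average
  base <- sin(seq(0, 2 * pi, length.out = 6))
  big <- withr::with_seed(1, {
    t(replicate(500, base * runif(1, 0.5, 2) + rnorm(6, sd = 0.1)))
  })
  rownames(big) <- sprintf("g%03d", 1:500)
  perm <- permute_matrix(big, seed = 1)
  cors <- cor(t(perm))
  mean_r <- mean(cors[upper.tri(cors)])
  expect_lt(abs(mean_r), 0.05)
  expect_gt(mean(cor(t(big))[upper.tri(cors)]), 0.5)

  expect_error(permute_matrix(matrix(c(1, NA), 1)), "finite")
})
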