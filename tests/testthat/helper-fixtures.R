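# Shared fixtures built in code.

# Small, fast simulation: 3 archetypes x 40 genes, 4 time points.
small_config <- function(seed = 1L, noise_sd = 0.1, n_genes = 40) {
  simulation_config(
    archetypes = list(
      archetype("up", c(6, 7, 8, 9), n_genes, noise_sd),
      archetype("down", c(9, 8, 7, 6), n_genes, noise_sd),
      archetype("pulse", c(6, 9, 9, 6), n_genes, noise_sd)
    ),
    times = c(0, 8, 24, 48),
    n_replicates = 3,
    seed = seed
  )
}

# The full study-scale configuration: 5 archetypes x 200 genes, 6 time
# points, 3 replicates, noise 0.2 (the package defaults).
study_config <- function(seed = 1L) {
  simulation_config(seed = seed)
}

# Two well-separated Gaussian blobs in the plane, for clustering sanity.
two_blobs <- function(n = 40, sep = 8, sd = 0.3, seed = 1L) {
  withr::with_seed(seed, {
    x <- rbind(
      matrix(rnorm(n * 2, 0, sd), n, 2),
      matrix(rnorm(n * 2, sep, sd), n, 2)
    )
    rownames(x) <- sprintf("g%03d", seq_len(2 * n))
    x
  })
}
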