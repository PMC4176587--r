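# Independent brute-force oracles, deliberately naive and separate from the
# package implementations they check.

# Literal Benjamini-Hochberg step-up: sort ascending, q_i = min_{j>=i} n*p_j/j,
# cap at 1, map back to the input order.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(n * ps[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Exhaustive upper-tail hypergeometric probability by direct enumeration of
# P(X = j) = C(K, j) C(N - K, n - j) / C(N, n) for j >= k.
hyper_upper_enum <- function(k, K, n, N) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Naive agglomerative complete linkage on a distance matrix: at each step
# merge the pair of clusters with the smallest maximum pairwise distance.
# Returns the merge heights in order.
linkage_bruteforce <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# Membership formula evaluated exactly as written, with double loops.
membership_bruteforce <- function(d, m) {
  u <- matrix(0, nrow(d), ncol(d))
  for (g in seq_len(nrow(d))) {
    for (j in seq_len(ncol(d))) {
      u[g, j] <- 1 / sum((d[g, j] / d[g, ])^(2 / (m - 1)))
    }
  }
  u
}

# Ordinary two-sample pooled-variance t-statistic from group summaries.
pooled_t <- function(mean_a, mean_b, s2_pooled, n_a, n_b) {
  (mean_a - mean_b) / sqrt(s2_pooled * (1 / n_a + 1 / n_b))
}
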