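#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` carry the annotation.  Evaluated
#' through the log-space distribution function for numerical stability.
#'
#' @param k Observed overlap.
#' @param K Annotated (term) genes in the universe.
#' @param n Drawn (cluster) genes.
#' @param N Universe size.
#'
#' @return The upper-tail probability; vectorized over all arguments.
#' @export
#' @examples
#' hypergeom_upper(4, 5, 4, 10) # 5/210
hypergeom_upper <- function(k, K, n, N) {
  ok <- k >= 0 & k <= pmin(K, n) & K <= N & n <= N & K >= 0 & n >= 0
  if (!all(ok)) abort("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N.")
  p <- exp(phyper(k - 1, m = K, n = N - K, k = n,
                  lower.tail = FALSE, log.p = TRUE))
  pmin(p, 1)
}

#' Over-representation of annotation terms within clusters
#'
#' One upper-tail hypergeometric test per (cluster, term) pair, for terms
#' with at least `min_term_size` genes in the universe.  Raw p-values are
#' primary; BH-adjusted p-values across the terms tested within each cluster
#' are reported as supplementary output.
#'
#' @param assignments Tibble with columns `gene` and `cluster` (NA clusters,
#'   e.g. unassigned genes, are kept in the universe but tested in no
#'   cluster); typically [hard_assignments()] output.
#' @param terms Named list of gene-id vectors (e.g. from [read_gmt()] or
#'   [simulate_term_map()]).
#' @param universe Gene universe; defaults to all genes in `assignments`
#'   (the measured set).  Term genes outside the universe are dropped.
#' @param min_term_size Minimal effective term size; default 3.
#'
#' @return Tibble with columns `cluster`, `term`, `k`, `K`, `n`, `N`,
#'   `p_raw`, `p_adj`, sorted by `p_raw`.
#' @export
enrich_clusters <- function(assignments, terms, universe = NULL,
                            min_term_size = 3) {
  if (!all(c("gene", "cluster") %in% names(assignments))) {
    abort("`assignments` needs columns gene and cluster.")
  }
  universe <- universe %||% unique(assignments$gene)
  if (length(universe) == 0L) abort("empty gene universe.")
  big_n <- length(universe)
  terms <- lapply(terms, intersect, universe)
  terms <- terms[vapply(terms, length, integer(1)) >= min_term_size]
  assigned <- dplyr::filter(assignments, !is.na(.data$cluster),
                            .data$gene %in% universe)
  if (nrow(assigned) == 0L || length(terms) == 0L) {
    return(tibble(cluster = character(0), term = character(0),
                  k = integer(0), K = integer(0), n = integer(0),
                  N = integer(0), p_raw = double(0), p_adj = double(0)))
  }
  clusters <- split(assigned$gene, assigned$cluster)
  rows <- lapply(names(clusters), function(cl) {
    cg <- clusters[[cl]]
    k <- vapply(terms, function(tg) length(intersect(tg, cg)), integer(1))
    big_k <- vapply(terms, length, integer(1))
    p <- hypergeom_upper(k, big_k, length(cg), big_n)
    tibble(cluster = cl, term = names(terms), k = k, K = big_k,
           n = length(cg), N = big_n, p_raw = p,
           p_adj = adjust_bh(p))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$p_raw)
}
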