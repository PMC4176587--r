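#' Select the fuzziness exponent on randomized data
#'
#' For each candidate `m`, the clustering is run on row-permuted
#' (structureless) versions of the data over several permutation seeds.
#' "Clusters detected" means the fraction of genes whose maximal membership
#' reaches `threshold` exceeds `detection_frac`: a sufficiently large `m`
#' collapses all centroids toward the grand mean on randomized data, pushing
#' every membership toward `1/c`.  The chosen `m` is the smallest grid value
#' at which no seed detects clusters, i.e. the softest setting that still
#' refuses to invent structure in noise.
#'
#' @param x Profile tibble or matrix (see [fcm_fit()]).
#' @param m_grid Ascending candidate exponents, all > 1.
#' @param centers Cluster count used during the screen.
#' @param n_seeds Permutation/initialization seeds per grid value.
#' @param detection_frac Fraction of high-membership genes above which
#'   clusters count as detected; default 0.01.
#' @param threshold Membership cut-off defining "high"; default 0.5.
#' @param seed Top-level seed.
#' @param ... Passed on to [fcm_fit()].
#'
#' @return Object of class `m_selection`: list with `m` (chosen value) and
#'   `diagnostics` (tibble: `m`, `seed`, `frac_high`, `detected`).
#' @export
select_m <- function(x, m_grid = c(1.05, 1.15, 1.25, 1.35, 1.5, 2),
                     centers = 5, n_seeds = 5, detection_frac = 0.01,
                     threshold = 0.5, seed = 1L, ...) {
  if (is.unsorted(m_grid, strictly = TRUE) || any(m_grid <= 1)) {
    abort("`m_grid` must be strictly ascending and > 1.")
  }
  xm <- as_profile_matrix(x)
  diag <- vector("list", length(m_grid) * n_seeds)
  i <- 0L
  for (m in m_grid) {
    for (s in seq_len(n_seeds)) {
      i <- i + 1L
      ps <- stage_seed(seed, i)
      perm <- permute_matrix(xm, seed = ps)
      fit <- fcm_fit(perm, centers = centers, m = m, seed = ps, ...)
      frac <- mean(apply(fit$memberships, 1L, max) >= threshold)
      diag[[i]] <- tibble(m = m, seed = s, frac_high = frac,
                          detected = frac > detection_frac)
    }
  }
  diag <- dplyr::bind_rows(diag)
  ok <- dplyr::summarise(dplyr::group_by(diag, .data$m),
                         clean = !any(.data$detected), .groups = "drop")
  passing <- ok$m[ok$clean]
  if (length(passing) == 0L) {
    abort("every candidate m detects clusters in randomized data; extend `m_grid` upward.")
  }
  structure(
    list(m = min(passing), diagnostics = diag, centers = centers,
         detection_frac = detection_frac, threshold = threshold),
    class = "m_selection"
  )
}

#' @export
print.m_selection <- function(x, ...) {
  cat(sprintf("Selected fuzziness exponent m = %.3g (c = %d during screen)\n",
              x$m, x$centers))
  invisible(x)
}

#' Tidy the fuzziness-selection diagnostics
#'
#' @param x An `m_selection` object.
#' @param ... Unused.
#' @return The diagnostics tibble (`m`, `seed`, `frac_high`, `detected`).
#' @method tidy m_selection
#' @export
tidy.m_selection <- function(x, ...) x$diagnostics

greedy_match_min_cor <- function(v1, v2) {
  cm <- suppressWarnings(cor(t(v1), t(v2)))
  cm[!is.finite(cm)] <- -1
  k <- nrow(cm)
  rs <- numeric(k)
  for (i in seq_len(k)) {
    ij <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    rs[i] <- cm[ij[1L], ij[2L]]
    cm[ij[1L], ] <- -Inf
    cm[, ij[2L]] <- -Inf
  }
  min(rs)
}

#' Select the number of clusters by membership anchoring and run stability
#'
#' A candidate `c` passes when (1) in every repeated run, each cluster
#' contains at least one gene with membership >= `threshold` (no cluster in
#' which all genes sit below the cut-off), and (2) the runs agree: for every
#' pair of repeated runs, greedily best-matched centroid pairs all reach a
#' Pearson profile correlation of at least `stability_r`.  The chosen `c` is
#' the largest grid value passing both, i.e. the finest partition that is
#' still anchored and reproducible.
#'
#' @param x Profile tibble or matrix.
#' @param c_grid Ascending candidate cluster counts, all >= 2.
#' @param m Fuzziness exponent; default 1.35.
#' @param n_repeats Repeated runs (different initialization seeds) per
#'   candidate.
#' @param threshold Membership anchor cut-off; default 0.5.
#' @param stability_r Minimal matched-centroid correlation; default 0.9.
#' @param seed Top-level seed.
#' @param ... Passed on to [fcm_fit()].
#'
#' @return Object of class `c_selection`: list with `c` (chosen value) and
#'   `diagnostics` (tibble: `c`, `anchored`, `min_matched_cor`, `pass`).
#' @export
select_c <- function(x, c_grid = 2:8, m = 1.35, n_repeats = 3,
                     threshold = 0.5, stability_r = 0.9, seed = 1L, ...) {
  if (is.unsorted(c_grid, strictly = TRUE) || any(c_grid < 2)) {
    abort("`c_grid` must be strictly ascending and >= 2.")
  }
  xm <- as_profile_matrix(x)
  rows <- vector("list", length(c_grid))
  for (k in seq_along(c_grid)) {
    cc <- c_grid[k]
    fits <- lapply(seq_len(n_repeats), function(r) {
      fcm_fit(xm, centers = cc, m = m,
              seed = stage_seed(seed, k * 100L + r), ...)
    })
    anchored <- all(vapply(fits, function(f) {
      all(apply(f$memberships, 2L, max) >= threshold)
    }, logical(1)))
    pairs <- utils::combn(n_repeats, 2L)
    min_cor <- min(apply(pairs, 2L, function(p) {
      greedy_match_min_cor(fits[[p[1L]]]$centroids, fits[[p[2L]]]$centroids)
    }))
    rows[[k]] <- tibble(c = cc, anchored = anchored,
                        min_matched_cor = min_cor,
                        pass = anchored && min_cor >= stability_r)
  }
  diag <- dplyr::bind_rows(rows)
  if (!any(diag$pass)) {
    print(diag)
    abort("no candidate c passes both the anchoring and stability criteria.")
  }
  structure(
    list(c = max(diag$c[diag$pass]), diagnostics = diag, m = m,
         threshold = threshold, stability_r = stability_r),
    class = "c_selection"
  )
}

#' @export
print.c_selection <- function(x, ...) {
  cat(sprintf("Selected cluster count c = %d (m = %.3g)\n", x$c, x$m))
  invisible(x)
}

#' Tidy the cluster-count-selection diagnostics
#'
#' @param x A `c_selection` object.
#' @param ... Unused.
#' @return The diagnostics tibble (`c`, `anchored`, `min_matched_cor`,
#'   `pass`).
#' @method tidy c_selection
#' @export
tidy.c_selection <- function(x, ...) x$diagnostics

#' Cross-tabulate two fuzzy clusterings of the same genes
#'
#' Genes are hard-assigned in each clustering (argmax membership when it
#' reaches `threshold`); the contingency table counts genes that a cluster of
#' `a` and a cluster of `b` have in common.  Genes unassigned in either
#' clustering are reported separately, never forced into the table.
#'
#' @param a,b [fcm_fit()] objects over the same gene universe.
#' @param threshold Hard-assignment membership cut-off; default 0.5.
#'
#' @return Object of class `cluster_contingency`: list with `counts`
#'   (clusters-of-a by clusters-of-b matrix), `unassigned` (named counts)
#'   and `threshold`.
#' @export
compare_clusterings <- function(a, b, threshold = 0.5) {
  stopifnot(inherits(a, "fcm_fit"), inherits(b, "fcm_fit"))
  ga <- rownames(a$memberships)
  gb <- rownames(b$memberships)
  if (!setequal(ga, gb)) abort("clusterings cover different gene universes.")
  ha <- hard_assignments(a, threshold)
  hb <- hard_assignments(b, threshold)
  hb <- hb[match(ha$gene, hb$gene), ]
  counts <- table(
    factor(ha$cluster, levels = colnames(a$memberships)),
    factor(hb$cluster, levels = colnames(b$memberships)),
    useNA = "no"
  )
  counts <- unclass(counts)
  names(dimnames(counts)) <- NULL
  structure(
    list(counts = counts,
         unassigned = c(a = sum(is.na(ha$cluster)),
                        b = sum(is.na(hb$cluster))),
         threshold = threshold),
    class = "cluster_contingency"
  )
}

#' @export
print.cluster_contingency <- function(x, ...) {
  cat(sprintf("Shared-gene contingency table (threshold %.2g)\n", x$threshold))
  print(x$counts)
  cat(sprintf("Unassigned: %d (rows), %d (columns)\n",
              x$unassigned[["a"]], x$unassigned[["b"]]))
  invisible(x)
}

#' Tidy a clustering contingency table
#'
#' @param x A `cluster_contingency` object.
#' @param ... Unused.
#' @return Long tibble with columns `cluster_a`, `cluster_b`, `n`.
#' @method tidy cluster_contingency
#' @export
tidy.cluster_contingency <- function(x, ...) {
  out <- as_tibble(as.table(x$counts), .name_repair = "minimal")
  names(out) <- c("cluster_a", "cluster_b", "n")
  out$n <- as.integer(out$n)
  out
}
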