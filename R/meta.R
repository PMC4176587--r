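#' Quantile normalization across study columns
#'
#' Forces every column to the identical value distribution: after
#' normalization each column's sorted values equal the per-rank row means of
#' the input's sorted columns, with ties receiving the mean of the tied
#' ranks' reference values.  Intended for complete blocks (no missing
#' values).
#'
#' @param x Numeric matrix, or data frame whose first column holds gene ids.
#'
#' @return Object of the same shape with identical sorted columns.  A single
#'   column is returned unchanged with a warning.
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
quantile_normalize <- function(x) {
  is_df <- is.data.frame(x)
  m <- as_profile_matrix(x)
  if (anyNA(m)) abort("quantile normalization requires a complete block (no NA).")
  if (ncol(m) < 2L) {
    warn("single column: quantile normalization is a no-op.")
    return(x)
  }
  q <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(q) <- dimnames(m)
  if (!is_df) return(q)
  as_tibble(q, rownames = names(x)[1L])
}

#' Sign-preserving scaling of log2 ratios to a common range
#'
#' Maps one study's log2 ratios onto `[lo, hi]` by a piecewise-linear map
#' through zero: positive values are multiplied by `hi / max(x)` and
#' negative values by `lo / min(x)`, so zero stays zero, no value changes
#' sign, the within-study gene ranking is unchanged, and the output never
#' leaves the target interval.  (An affine min-max map would shift the zero
#' point and corrupt the up/down semantics of log2 ratios.)
#'
#' @param x Numeric vector of log2 ratios (NA allowed and passed through).
#' @param range Target interval `c(lo, hi)` with `lo < 0 < hi`; default the
#'   common range `c(-4.03, 4.07)`.
#'
#' @return The scaled vector.  All-zero input is returned unchanged with a
#'   warning.
#' @export
scale_to_range <- function(x, range = c(-4.03, 4.07)) {
  lo <- range[1L]
  hi <- range[2L]
  if (!(lo < 0 && 0 < hi)) abort("`range` must satisfy lo < 0 < hi.")
  obs <- x[!is.na(x)]
  if (length(obs) == 0L || all(obs == 0)) {
    warn("no nonzero values; returned unchanged.")
    return(x)
  }
  out <- x
  if (any(obs > 0)) {
    f <- hi / max(obs)
    out[!is.na(x) & x > 0] <- x[!is.na(x) & x > 0] * f
  }
  if (any(obs < 0)) {
    f <- lo / min(obs)
    out[!is.na(x) & x < 0] <- x[!is.na(x) & x < 0] * f
  }
  pmin(pmax(out, lo), hi)
}

#' Select genes recurrently significant across studies
#'
#' @param studies Long tibble with columns `study`, `gene`, `significant`
#'   (logical or 0/1), e.g. from [simulate_multistudy()] or
#'   [read_study_tsv()].
#' @param min_count Minimal number of studies in which a gene must be
#'   flagged significant; default 2 ("significant in at least two of the
#'   comparisons").
#'
#' @return Tibble with columns `gene`, `n_significant`, `selected`.
#' @export
select_recurrent <- function(studies, min_count = 2) {
  if (!all(c("study", "gene", "significant") %in% names(studies))) {
    abort("`studies` needs columns study, gene, significant.")
  }
  if (dplyr::n_distinct(studies$study) < 2L) {
    abort("need at least two studies.")
  }
  out <- dplyr::summarise(
    dplyr::group_by(studies, .data$gene),
    n_significant = sum(as.logical(.data$significant), na.rm = TRUE),
    .groups = "drop"
  )
  dplyr::mutate(out, selected = .data$n_significant >= min_count)
}

#' Complete-linkage hierarchical clustering of a matrix axis
#'
#' Agglomerative clustering with Euclidean distances where the distance
#' between two clusters is the maximum pairwise item distance, so merge
#' heights are non-decreasing.  Missing values are imputed to 0 for the
#' distance computation, with a warning.
#'
#' @param x Numeric matrix or data frame with a leading gene-id column.
#' @param axis Cluster `"rows"` (default) or `"columns"`.
#'
#' @return An [stats::hclust] object with item labels.
#' @export
hclust_complete <- function(x, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- as_profile_matrix(x)
  if (axis == "columns") m <- t(m)
  if (nrow(m) < 2L) abort("need at least two items to cluster.")
  if (anyNA(m)) {
    warn(sprintf("%d missing value(s) imputed to 0 for clustering distances.",
                 sum(is.na(m))))
    m[is.na(m)] <- 0
  }
  hclust(dist(m, method = "euclidean"), method = "complete")
}

#' Leaf sets of every internal dendrogram node
#'
#' @param hc An [stats::hclust] object.
#' @return List of character vectors, one per merge, each the labels under
#'   that node.
#' @export
dendrogram_leaf_sets <- function(hc) {
  labs <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- lapply(hc$merge[i, ], function(j) {
      if (j < 0) labs[-j] else sets[[j]]
    })
    sets[[i]] <- c(members[[1L]], members[[2L]])
  }
  sets
}

#' Do the given leaves form one dendrogram subtree?
#'
#' TRUE when some node of the tree has exactly `labels` as its leaf set (a
#' single leaf trivially forms a subtree).
#'
#' @param hc An [stats::hclust] object.
#' @param labels Character vector of leaf labels.
#' @return Logical scalar.
#' @export
leaves_form_subtree <- function(hc, labels) {
  labels <- unique(as.character(labels))
  if (length(labels) == 1L) return(labels %in% hc$labels)
  any(vapply(dendrogram_leaf_sets(hc), setequal, logical(1), labels))
}

#' Export a dendrogram as a newick string
#'
#' @param hc An [stats::hclust] object.
#' @return A newick-format character scalar.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Integrate multiple study comparisons into an ordered heatmap matrix
#'
#' The cross-study pipeline: per-study log2 ratios are quantile-normalized
#' (complete columns only; columns with missing genes bypass normalization),
#' each study is scaled to the common range with the sign-preserving map,
#' recurrently significant genes are selected, and both axes of the
#' resulting matrix are ordered by complete-linkage hierarchical clustering.
#'
#' @param studies Long tibble with columns `study`, `gene`, `log2_ratio`,
#'   `significant`.
#' @param min_count Recurrence threshold for gene selection; default 2.
#' @param range Common log2-ratio range; default `c(-4.03, 4.07)`.
#'
#' @return Object of class `integrated_matrix`: list with `values` (selected
#'   genes x studies, scaled; NA where a study lacks a gene), `row_hclust`,
#'   `col_hclust`, `row_order`, `col_order` (label vectors), `counts` (the
#'   [select_recurrent()] table) and `range`.
#' @export
build_heatmap_matrix <- function(studies, min_count = 2,
                                 range = c(-4.03, 4.07)) {
  needed <- c("study", "gene", "log2_ratio", "significant")
  if (!all(needed %in% names(studies))) {
    abort("`studies` needs columns study, gene, log2_ratio, significant.")
  }
  wide <- tidyr::pivot_wider(
    dplyr::distinct(studies, .data$study, .data$gene, .data$log2_ratio),
    names_from = "study", values_from = "log2_ratio"
  )
  m <- as_profile_matrix(wide)

  complete_cols <- colnames(m)[colSums(is.na(m)) == 0L]
  if (length(complete_cols) >= 2L) {
    m[, complete_cols] <- quantile_normalize(m[, complete_cols, drop = FALSE])
  }
  skipped <- setdiff(colnames(m), complete_cols)
  if (length(skipped) > 0L) {
    inform(sprintf("%d study column(s) with missing genes bypass quantile normalization.",
                   length(skipped)))
  }
  m <- apply(m, 2L, scale_to_range, range = range)

  counts <- select_recurrent(studies, min_count = min_count)
  sel <- counts$gene[counts$selected]
  if (length(sel) < 2L) {
    abort("fewer than two recurrently significant genes; nothing to cluster.")
  }
  sub <- m[sel, , drop = FALSE]

  row_hc <- suppressWarnings(hclust_complete(sub, axis = "rows"))
  col_hc <- suppressWarnings(hclust_complete(sub, axis = "columns"))
  structure(
    list(values = sub,
         row_hclust = row_hc, col_hclust = col_hc,
         row_order = rownames(sub)[row_hc$order],
         col_order = colnames(sub)[col_hc$order],
         counts = counts, range = range),
    class = "integrated_matrix"
  )
}

#' @export
print.integrated_matrix <- function(x, ...) {
  cat(sprintf(
    "Integrated log2-ratio matrix: %d genes x %d studies, range [%.3g, %.3g]\n",
    nrow(x$values), ncol(x$values), x$range[1L], x$range[2L]
  ))
  invisible(x)
}

#' Tidy an integrated matrix into a long, display-ordered table
#'
#' @param x An `integrated_matrix` object.
#' @param ... Unused.
#' @return Long tibble with columns `gene`, `study`, `log2_ratio`; `gene`
#'   and `study` are factors in dendrogram leaf order.
#' @method tidy integrated_matrix
#' @export
tidy.integrated_matrix <- function(x, ...) {
  out <- as_tibble(x$values, rownames = "gene")
  out <- tidyr::pivot_longer(out, -"gene", names_to = "study",
                             values_to = "log2_ratio")
  out$gene <- factor(out$gene, levels = x$row_order)
  out$study <- factor(out$study, levels = x$col_order)
  out
}
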