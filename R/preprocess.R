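#' Average replicates within each (strain, time) cell
#'
#' @param expr Long expression tibble with columns `gene`, `strain`,
#'   `time_h`, `replicate`, `value` (as produced by [simulate_timecourse()]
#'   or [read_expression_tsv()]).
#'
#' @return Tibble with columns `gene`, `strain`, `time_h`, `value`, one row
#'   per gene and (strain, time) cell.
#' @export
average_replicates <- function(expr) {
  needed <- c("gene", "strain", "time_h", "value")
  if (!all(needed %in% names(expr))) {
    abort("`expr` needs columns gene, strain, time_h, value.")
  }
  grid <- tidyr::expand_grid(strain = unique(expr$strain),
                             time_h = sort(unique(expr$time_h)))
  present <- dplyr::distinct(expr, .data$strain, .data$time_h)
  missing <- dplyr::anti_join(grid, present, by = c("strain", "time_h"))
  if (nrow(missing) > 0L) {
    abort(sprintf("no replicates for cell (%s, %g h).",
                  missing$strain[1L], missing$time_h[1L]))
  }
  out <- dplyr::summarise(
    dplyr::group_by(expr, .data$gene, .data$strain, .data$time_h),
    value = mean(.data$value), .groups = "drop"
  )
  dplyr::arrange(out, .data$gene, .data$strain, .data$time_h)
}

#' Normalized (z-scored) expression profiles
#'
#' Scales and centres each gene's replicate-averaged trajectory to mean 0 and
#' standard deviation 1 (sample standard deviation, n - 1 denominator),
#' emphasizing profile shape over magnitude.  With more than one strain the
#' trajectories are concatenated strain-by-strain and scaled as one vector,
#' so both strains' shapes appear in a single profile; pass a single strain
#' to scale per strain instead.  Zero-variance rows cannot be scaled: they
#' are flagged degenerate, excluded from the output and reported in the
#' `degenerate` attribute.
#'
#' @param averaged Output of [average_replicates()].
#' @param strains Strains to include, in order; default all strains present.
#'
#' @return A wide tibble (class `profile_tbl`): column `gene` plus one column
#'   per (strain, time) coordinate, with attributes `view = "NP"`, `times`,
#'   `strains` and `degenerate` (excluded gene ids).
#' @export
normalized_profiles <- function(averaged, strains = NULL) {
  strains <- strains %||% unique(averaged$strain)
  sub <- dplyr::filter(averaged, .data$strain %in% strains)
  if (nrow(sub) == 0L) abort("selected strains not present.")
  times <- sort(unique(sub$time_h))
  if (length(times) < 2L) abort("need at least two time points.")
  coord_levels <- sprintf("%s_%gh", rep(strains, each = length(times)),
                          rep(times, length(strains)))
  sub$coord <- sprintf("%s_%gh", sub$strain, sub$time_h)
  wide <- tidyr::pivot_wider(
    dplyr::select(sub, "gene", "coord", "value"),
    names_from = "coord", values_from = "value"
  )
  wide <- wide[, c("gene", coord_levels)]
  m <- as_profile_matrix(wide)
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  degenerate <- rownames(m)[s < 1e-12]
  if (length(degenerate) > 0L) {
    inform(sprintf("%d zero-variance gene(s) flagged degenerate and excluded.",
                   length(degenerate)))
  }
  keep <- s >= 1e-12
  z <- (m[keep, , drop = FALSE] - mu[keep]) / s[keep]
  out <- as_tibble(z, rownames = "gene")
  structure(out, class = c("profile_tbl", class(out)),
            view = "NP", times = times, strains = strains,
            degenerate = degenerate)
}

#' Fold-change (log2 ratio) profiles between two strains
#'
#' Per gene and time point, the producer strain's replicate-averaged log2
#' intensity minus the control strain's.  A value of -1 means 2-fold
#' down-regulation and +1 means 2-fold up-regulation in the producer relative
#' to the control; no row scaling is applied, so up- and down-regulation get
#' equal weight.
#'
#' @param averaged Output of [average_replicates()].
#' @param producer,control Strain labels.
#'
#' @return A wide tibble (class `profile_tbl`): column `gene` plus one column
#'   per time point, with attributes `view = "FC"`, `times` and
#'   `strain_context`.
#' @export
fold_change_profiles <- function(averaged, producer, control) {
  have <- unique(averaged$strain)
  if (!all(c(producer, control) %in% have)) {
    abort("both strains must be present in `averaged`.")
  }
  tp <- sort(unique(averaged$time_h[averaged$strain == producer]))
  tc <- sort(unique(averaged$time_h[averaged$strain == control]))
  if (!identical(tp, tc)) abort("strains measured on different time grids.")
  wide <- tidyr::pivot_wider(
    dplyr::filter(averaged, .data$strain %in% c(producer, control)),
    names_from = "strain", values_from = "value"
  )
  wide$fc <- wide[[producer]] - wide[[control]]
  out <- tidyr::pivot_wider(
    dplyr::transmute(wide, .data$gene,
                     coord = sprintf("%gh", .data$time_h), .data$fc),
    names_from = "coord", values_from = "fc"
  )
  out <- out[, c("gene", sprintf("%gh", tp))]
  structure(out, class = c("profile_tbl", class(out)),
            view = "FC", times = tp,
            strain_context = c(producer = producer, control = control))
}

#' Relative expression from qPCR threshold cycles
#'
#' Converts threshold-cycle (Ct) values to relative template abundance
#' assuming perfect doubling per cycle (abundance proportional to
#' `2^(-Ct)`), expressed as a percentage of the maximal abundance across
#' conditions; the maximum is exactly 100.
#'
#' @param ct Numeric vector of Ct values, one per condition.
#'
#' @return Numeric vector of percentages of the maximal expression.
#' @export
#' @examples
#' relative_expression_from_ct(c(20, 21))    # 100, 50
#' relative_expression_from_ct(c(20, 20, 23)) # 100, 100, 12.5
relative_expression_from_ct <- function(ct) {
  if (length(ct) == 0L) abort("`ct` must not be empty.")
  if (!all(is.finite(ct))) abort("`ct` must be finite.")
  100 * 2^(-(ct - min(ct)))
}
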