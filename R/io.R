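#' Write an expression dataset as value + metadata TSV files
#'
#' Values are written genes-by-samples with a `gene` column and one column
#' per sample id; metadata holds one row per sample (`sample`, `strain`,
#' `time_h`, `replicate`).
#'
#' @param expr Long expression tibble (see [simulate_timecourse()]).
#' @param values_path,metadata_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_expression_tsv <- function(expr, values_path, metadata_path) {
  wide <- tidyr::pivot_wider(
    dplyr::distinct(expr, .data$gene, .data$sample, .data$value),
    names_from = "sample", values_from = "value"
  )
  readr::write_tsv(wide, values_path)
  meta <- dplyr::distinct(expr, .data$sample, .data$strain, .data$time_h,
                          .data$replicate)
  readr::write_tsv(meta, metadata_path)
  invisible(c(values_path, metadata_path))
}

#' Read an expression dataset from value + metadata TSV files
#'
#' @param values_path TSV with a `gene` column and one numeric column per
#'   sample.
#' @param metadata_path TSV with columns `sample`, `strain`, `time_h`,
#'   `replicate` covering every sample column.
#' @return Long expression tibble with columns `gene`, `sample`, `strain`,
#'   `time_h`, `replicate`, `value`.
#' @export
read_expression_tsv <- function(values_path, metadata_path) {
  wide <- readr::read_tsv(values_path, show_col_types = FALSE,
                          progress = FALSE)
  if (names(wide)[1L] != "gene") abort("first column must be `gene`.")
  dup <- wide$gene[duplicated(wide$gene)]
  if (length(dup) > 0L) {
    abort(sprintf("duplicate gene identifier: %s", dup[1L]))
  }
  for (j in seq_along(wide)[-1L]) {
    if (!is.numeric(wide[[j]])) {
      abort(sprintf("non-numeric values in sample column '%s'.",
                    names(wide)[j]))
    }
  }
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  needed <- c("sample", "strain", "time_h", "replicate")
  if (!all(needed %in% names(meta))) {
    abort("metadata needs columns sample, strain, time_h, replicate.")
  }
  samples <- names(wide)[-1L]
  missing <- setdiff(samples, meta$sample)
  if (length(missing) > 0L) {
    abort(sprintf("metadata missing sample: %s", missing[1L]))
  }
  unknown <- setdiff(meta$sample, samples)
  if (length(unknown) > 0L) {
    abort(sprintf("metadata lists unknown sample: %s", unknown[1L]))
  }
  long <- tidyr::pivot_longer(wide, -"gene", names_to = "sample",
                              values_to = "value")
  long <- dplyr::left_join(long, meta, by = "sample")
  dplyr::select(long, "gene", "sample", "strain", "time_h", "replicate",
                "value")
}

#' Read a GMT term-to-gene file
#'
#' Standard tab-separated GMT: term id, description, then one or more gene
#' ids per line.
#'
#' @param path GMT file path.
#' @return Named list of gene-id vectors with a `description` attribute; an
#'   empty file yields an empty list.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(structure(list(), description = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("line %d: GMT lines need term, description and >= 1 gene.",
                  bad[1L]))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate term id: %s", ids[duplicated(ids)][1L]))
  }
  terms <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(terms) <- ids
  structure(terms,
            description = setNames(vapply(fields, `[[`, character(1), 2L), ids))
}

#' Write a term map as a GMT file
#'
#' @param terms Named list of gene-id vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to the term id.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(terms, path, descriptions = NULL) {
  desc <- descriptions %||% setNames(names(terms), names(terms))
  lines <- vapply(names(terms), function(id) {
    paste(c(id, desc[[id]] %||% id, terms[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a profile matrix as TSV with a view header
#'
#' The first line is a `#`-prefixed comment recording the view, strains and
#' times, so the file round-trips through [read_profile_tsv()].
#'
#' @param profiles A `profile_tbl` (see [normalized_profiles()],
#'   [fold_change_profiles()]).
#' @param path Output path.
#' @param extra Optional additional `key=value` strings for the header.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(profiles, path, extra = character(0)) {
  hdr <- c(
    paste0("view=", attr(profiles, "view") %||% "NA"),
    paste0("times=", paste(attr(profiles, "times"), collapse = ",")),
    paste0("strains=", paste(attr(profiles, "strains") %||%
                               attr(profiles, "strain_context"),
                             collapse = ",")),
    extra
  )
  writeLines(paste("#", paste(hdr, collapse = " ")), path)
  readr::write_tsv(as_tibble(profiles), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a profile matrix written by [write_profile_tsv()]
#'
#' @param path TSV path.
#' @return A `profile_tbl` with the `view` attribute restored.
#' @export
read_profile_tsv <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  hdr <- readLines(path, n = 1L)
  view <- sub(".*view=(\\S+).*", "\\1", hdr)
  structure(out, class = c("profile_tbl", class(out)), view = view)
}

#' Read a per-study comparison table
#'
#' @param path TSV with columns `gene`, `log2_ratio`, `significant` (0/1 or
#'   logical).
#' @param study Study identifier attached to every row.
#' @return Long tibble with columns `study`, `gene`, `log2_ratio`,
#'   `significant`.
#' @export
read_study_tsv <- function(path, study) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("gene", "log2_ratio", "significant")
  if (!all(needed %in% names(out))) {
    abort("study table needs columns gene, log2_ratio, significant.")
  }
  out <- dplyr::select(out, dplyr::all_of(needed))
  out$significant <- as.logical(out$significant)
  out$study <- study
  dplyr::select(out, "study", "gene", "log2_ratio", "significant")
}
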