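#' Define a temporal expression archetype
#'
#' An archetype is a template expression trajectory on the log2 scale from
#' which genes are simulated.  The producer strain can additionally receive a
#' per-time-point offset, which models strain-specific induction or a
#' constitutive strain difference.
#'
#' @param name Archetype label.
#' @param base_profile Numeric vector of per-time-point means (log2 scale),
#'   one value per time point.
#' @param n_genes Number of genes drawn from this archetype.
#' @param noise_sd Standard deviation of the additive Gaussian replicate
#'   noise, in log2 units.
#' @param strain_effect Additive offset applied to the producer strain only;
#'   either a scalar or a vector with one value per time point.
#'
#' @return An object of class `archetype`.
#' @export
#' @examples
#' archetype("up", base_profile = c(6, 7, 8), n_genes = 50)
archetype <- function(name, base_profile, n_genes, noise_sd = 0.2,
                      strain_effect = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.")
  }
  base_profile <- as.double(base_profile)
  if (length(base_profile) < 2L || anyNA(base_profile)) {
    abort("`base_profile` needs at least two finite values.")
  }
  if (n_genes < 1L) abort("`n_genes` must be >= 1.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  strain_effect <- as.double(strain_effect)
  if (length(strain_effect) == 1L) {
    strain_effect <- rep(strain_effect, length(base_profile))
  }
  if (length(strain_effect) != length(base_profile)) {
    abort("`strain_effect` must be scalar or match `base_profile` in length.")
  }
  structure(
    list(name = name, base_profile = base_profile,
         n_genes = as.integer(n_genes), noise_sd = noise_sd,
         strain_effect = strain_effect),
    class = "archetype"
  )
}

#' Default archetype set for the two-strain time-course simulator
#'
#' Five temporal archetypes over the default six-point sampling grid:
#' steady up-regulation, steady down-regulation, a transient pulse, a
#' producer-specific delayed induction, and a flat trajectory with a constant
#' producer offset (a constitutive strain difference).  Each archetype has a
#' distinct normalized-profile shape over the concatenated two-strain
#' trajectory, so the planted partition is identifiable from profile shape
#' alone.
#'
#' @param n_genes Genes per archetype.
#' @param noise_sd Replicate noise standard deviation in log2 units.
#'
#' @return A list of [archetype()] objects.
#' @export
default_archetypes <- function(n_genes = 200, noise_sd = 0.2) {
  list(
    archetype("steady_up",  c(6.0, 6.6, 7.2, 7.8, 8.4, 9.0), n_genes, noise_sd),
    archetype("steady_down", c(9.0, 8.4, 7.8, 7.2, 6.6, 6.0), n_genes, noise_sd),
    archetype("transient",  c(7.0, 8.5, 9.5, 8.5, 7.3, 7.0), n_genes, noise_sd),
    archetype("delayed",    rep(7, 6), n_genes, noise_sd,
              strain_effect = c(0, 0, 0, 1, 2, 3)),
    archetype("flat",       rep(8, 6), n_genes, noise_sd,
              strain_effect = 1.5)
  )
}

#' Simulation configuration for a two-strain time course
#'
#' @param archetypes List of [archetype()] objects; all base profiles must
#'   share one length, the number of time points.
#' @param times Numeric vector of sampling times in hours (default: the
#'   six-point bioreactor sampling grid 0, 7, 23, 47, 49, 71 h).
#' @param n_replicates Independent cultures per strain.
#' @param strains Length-2 character vector, producer first.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#'
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(archetypes = default_archetypes(),
                              times = c(0, 7, 23, 47, 49, 71),
                              n_replicates = 3,
                              strains = c("producer", "control"),
                              seed = 1L) {
  if (length(archetypes) == 0L) abort("`archetypes` must not be empty.")
  if (!all(vapply(archetypes, inherits, logical(1), "archetype"))) {
    abort("`archetypes` must be a list of archetype() objects.")
  }
  if (length(times) < 2L) abort("need at least two time points.")
  if (anyDuplicated(times)) abort("`times` must be distinct.")
  lens <- vapply(archetypes, function(a) length(a$base_profile), integer(1))
  if (!all(lens == length(times))) {
    abort("every base_profile must have one value per time point.")
  }
  if (n_replicates < 1L) abort("`n_replicates` must be >= 1.")
  strains <- as.character(strains)
  if (length(strains) != 2L || anyDuplicated(strains)) {
    abort("`strains` must be two distinct labels (producer first).")
  }
  if (length(seed) != 1L || is.na(seed)) abort("`seed` is mandatory.")
  nm <- vapply(archetypes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort("archetype names must be unique.")
  structure(
    list(archetypes = archetypes, times = as.double(times),
         n_replicates = as.integer(n_replicates), strains = strains,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a two-strain time-course expression dataset
#'
#' Each gene is drawn from one archetype: its value in strain `s`, time `t`,
#' replicate `r` is the archetype mean at `t` (plus the strain effect if `s`
#' is the producer) plus Gaussian noise.  The gene-to-archetype ground truth
#' is returned alongside the dataset, never embedded in the identifiers.
#'
#' @param config A [simulation_config()].
#'
#' @return A list of class `timecourse_sim` with elements
#'   * `expression`: long tibble with columns `gene`, `sample`, `strain`,
#'     `time_h`, `replicate`, `value`;
#'   * `truth`: tibble with columns `gene`, `archetype`;
#'   * `config`: the configuration used.
#' @export
#' @examples
#' sim <- simulate_timecourse(simulation_config(seed = 7))
#' dplyr::count(sim$expression, strain, time_h)
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  times <- config$times
  n_t <- length(times)
  n_r <- config$n_replicates
  strains <- config$strains
  n_genes <- vapply(config$archetypes, `[[`, integer(1), "n_genes")
  g_total <- sum(n_genes)
  genes <- sprintf("g%05d", seq_len(g_total))
  arch_of <- rep(vapply(config$archetypes, `[[`, character(1), "name"), n_genes)

  base <- do.call(rbind, lapply(config$archetypes, function(a) {
    matrix(a$base_profile, a$n_genes, n_t, byrow = TRUE)
  }))
  offset <- do.call(rbind, lapply(config$archetypes, function(a) {
    matrix(a$strain_effect, a$n_genes, n_t, byrow = TRUE)
  }))
  noise_sd <- rep(vapply(config$archetypes, `[[`, double(1), "noise_sd"),
                  n_genes)

  cols <- expand.grid(replicate = seq_len(n_r), time_h = times,
                      strain = strains, stringsAsFactors = FALSE)
  cols <- cols[order(match(cols$strain, strains), cols$time_h, cols$replicate), ]
  sample_id <- sprintf("%s_%gh_r%d", cols$strain, cols$time_h, cols$replicate)

  mean_mat <- matrix(0, g_total, nrow(cols))
  for (j in seq_len(nrow(cols))) {
    ti <- match(cols$time_h[j], times)
    mean_mat[, j] <- base[, ti] +
      if (cols$strain[j] == strains[1L]) offset[, ti] else 0
  }
  values <- withr::with_seed(config$seed, {
    mean_mat + matrix(rnorm(g_total * nrow(cols), sd = noise_sd),
                      g_total, nrow(cols))
  })
  dimnames(values) <- list(genes, sample_id)

  expr <- as_tibble(values, rownames = "gene")
  expr <- tidyr::pivot_longer(expr, -"gene", names_to = "sample",
                              values_to = "value")
  meta <- tibble(sample = sample_id, strain = cols$strain,
                 time_h = cols$time_h, replicate = cols$replicate)
  expr <- dplyr::left_join(expr, meta, by = "sample")
  expr <- dplyr::select(expr, "gene", "sample", "strain", "time_h",
                        "replicate", "value")

  structure(
    list(expression = expr,
         truth = tibble(gene = genes, archetype = arch_of),
         config = config),
    class = "timecourse_sim"
  )
}

#' Convert a long expression tibble to a gene-by-sample matrix
#'
#' @param expr Long tibble with columns `gene`, `sample`, `value`.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
expression_matrix <- function(expr) {
  wide <- tidyr::pivot_wider(
    dplyr::distinct(expr, .data$gene, .data$sample, .data$value),
    names_from = "sample", values_from = "value"
  )
  as_profile_matrix(wide)
}

#' Default planted-term configuration
#'
#' One strongly planted term per informative archetype plus one background
#' term with no planted enrichment, for exercising over-representation tests.
#'
#' @return Tibble with columns `term`, `archetype`, `n_in_term`,
#'   `n_background`.
#' @export
default_term_config <- function() {
  tibble(
    term = c("T_up", "T_delayed", "T_transient", "T_background"),
    archetype = c("steady_up", "delayed", "transient", NA),
    n_in_term = c(60L, 60L, 60L, 0L),
    n_background = c(0L, 20L, 10L, 50L)
  )
}

#' Simulate a term-to-gene annotation map with planted enrichment
#'
#' Each term receives `n_in_term` genes sampled from its source archetype and
#' `n_background` genes sampled from the remaining genes.  Serializable with
#' [write_gmt()].
#'
#' @param config A [simulation_config()] (supplies the seed).
#' @param truth Gene-to-archetype tibble as returned by
#'   [simulate_timecourse()].
#' @param term_config Tibble with columns `term`, `archetype`, `n_in_term`,
#'   `n_background`; defaults to [default_term_config()].
#'
#' @return Named list of gene-id character vectors, one per term.
#' @export
simulate_term_map <- function(config, truth,
                              term_config = default_term_config()) {
  stopifnot(inherits(config, "sim_config"),
            all(c("gene", "archetype") %in% names(truth)))
  needed <- c("term", "archetype", "n_in_term", "n_background")
  if (!all(needed %in% names(term_config))) {
    abort("`term_config` needs columns term, archetype, n_in_term, n_background.")
  }
  known <- unique(truth$archetype)
  src <- term_config$archetype
  if (!all(is.na(src) | src %in% known)) {
    abort("`term_config` references archetypes absent from the truth map.")
  }
  withr::with_seed(stage_seed(config$seed, 2L), {
    out <- vector("list", nrow(term_config))
    names(out) <- term_config$term
    for (i in seq_len(nrow(term_config))) {
      a <- term_config$archetype[i]
      in_pool <- if (is.na(a)) character(0) else truth$gene[truth$archetype == a]
      k_in <- term_config$n_in_term[i]
      if (k_in > length(in_pool)) {
        abort(sprintf("term '%s': n_in_term (%d) exceeds archetype size (%d).",
                      term_config$term[i], k_in, length(in_pool)))
      }
      bg_pool <- setdiff(truth$gene, in_pool)
      k_bg <- min(term_config$n_background[i], length(bg_pool))
      out[[i]] <- c(
        if (k_in > 0) sample(in_pool, k_in) else character(0),
        if (k_bg > 0) sample(bg_pool, k_bg) else character(0)
      )
    }
    out
  })
}

#' Simulate a multi-study log2-ratio collection with planted modules
#'
#' Emulates a combined set of case-versus-control comparisons from multiple
#' studies.  Each module assigns one log2 effect to a gene set in a subset of
#' studies; everything else is Gaussian noise.  A gene is flagged significant
#' in a study when its absolute log2 ratio exceeds `sig_threshold`.
#'
#' @param n_studies Number of study comparisons.
#' @param n_genes Size of the shared gene universe.
#' @param modules List of modules, each a list with elements `genes`
#'   (character ids or integer indices into the universe), `studies`
#'   (integer study indices) and `effect` (log2 units).
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param sig_threshold Absolute log2-ratio threshold for the significance
#'   flag.
#' @param seed Integer seed.
#'
#' @return A list of class `multistudy_sim` with `studies` (long tibble:
#'   `study`, `gene`, `log2_ratio`, `significant`) and `truth` (the module
#'   list with gene ids resolved).
#' @export
simulate_multistudy <- function(n_studies = 20, n_genes = 1000,
                                modules = list(), noise_sd = 0.2,
                                sig_threshold = 1, seed = 1L) {
  if (n_studies < 1L || n_genes < 1L) abort("need >= 1 study and >= 1 gene.")
  genes <- sprintf("g%05d", seq_len(n_genes))
  studies <- sprintf("study%02d", seq_len(n_studies))

  effect <- matrix(0, n_genes, n_studies, dimnames = list(genes, studies))
  touched <- matrix(FALSE, n_genes, n_studies)
  modules <- lapply(modules, function(m) {
    gi <- if (is.numeric(m$genes)) as.integer(m$genes) else match(m$genes, genes)
    if (anyNA(gi) || any(gi < 1L | gi > n_genes)) {
      abort("module gene set outside the universe.")
    }
    si <- as.integer(m$studies)
    if (any(si < 1L | si > n_studies)) abort("module study index out of range.")
    for (s in si) {
      clash <- touched[gi, s] & effect[gi, s] != m$effect
      if (any(clash)) {
        abort("conflicting module effects for at least one (gene, study) pair.")
      }
      touched[gi, s] <<- TRUE
      effect[gi, s] <<- m$effect
    }
    list(genes = genes[gi], studies = si, effect = m$effect)
  })

  ratios <- withr::with_seed(as.integer(seed), {
    effect + matrix(rnorm(n_genes * n_studies, sd = noise_sd),
                    n_genes, n_studies)
  })
  long <- as_tibble(ratios, rownames = "gene")
  long <- tidyr::pivot_longer(long, -"gene", names_to = "study",
                              values_to = "log2_ratio")
  long$significant <- abs(long$log2_ratio) > sig_threshold
  long <- dplyr::select(long, "study", "gene", "log2_ratio", "significant")

  structure(list(studies = long, truth = modules), class = "multistudy_sim")
}

#' Row-wise permutation of a matrix
#'
#' Independently permutes each row's values across columns, preserving every
#' per-row value multiset while destroying any column (temporal) structure.
#' This is the randomization used when selecting the fuzziness exponent on a
#' structureless version of the data.
#'
#' @param x Numeric matrix, or data frame whose first column holds gene ids.
#' @param seed Integer seed.
#'
#' @return An object of the same shape as `x` with rows permuted.
#' @export
permute_matrix <- function(x, seed = 1L) {
  is_df <- is.data.frame(x)
  m <- as_profile_matrix(x)
  if (!all(is.finite(m))) abort("`x` must be finite.")
  p <- withr::with_seed(as.integer(seed), {
    t(apply(m, 1L, sample))
  })
  dimnames(p) <- dimnames(m)
  if (!is_df) return(p)
  out <- as_tibble(p, rownames = names(x)[1L])
  attributes(out)$view <- attr(x, "view")
  out
}
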