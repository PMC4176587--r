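#' Build and validate a pipeline configuration
#'
#' All numeric parameters are checked before any computation; all randomness
#' downstream flows from `seed` through a per-stage counter, so re-running
#' with the same configuration reproduces every output.
#'
#' @param seed Top-level integer seed.
#' @param archetypes List of [archetype()] objects for the simulator.
#' @param times,n_replicates,strains Passed to [simulation_config()].
#' @param m Fuzziness exponent for both clustering views.
#' @param c_np,c_fc Cluster counts for the normalized-profile and
#'   fold-change views.
#' @param contrast_times Times (h) at which producer-vs-control contrasts
#'   are tested.
#' @param p_cut,lfc_cut Significance thresholds (BH-adjusted p, |log2 FC|).
#' @param term_config Planted-term configuration for enrichment fixtures.
#'
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            archetypes = default_archetypes(),
                            times = c(0, 7, 23, 47, 49, 71),
                            n_replicates = 3,
                            strains = c("producer", "control"),
                            m = 1.35, c_np = 5, c_fc = 3,
                            contrast_times = c(47),
                            p_cut = 1e-05, lfc_cut = 1,
                            term_config = default_term_config()) {
  if (m <= 1) abort("`m` must be > 1.")
  if (c_np < 2 || c_fc < 2) abort("cluster counts must be >= 2.")
  if (p_cut <= 0 || p_cut > 1) abort("`p_cut` must be in (0, 1].")
  if (lfc_cut < 0) abort("`lfc_cut` must be >= 0.")
  if (!all(contrast_times %in% times)) {
    abort("`contrast_times` must be a subset of `times`.")
  }
  sim <- simulation_config(archetypes = archetypes, times = times,
                           n_replicates = n_replicates, strains = strains,
                           seed = seed)
  structure(
    list(seed = as.integer(seed), sim = sim, m = m,
         c_np = as.integer(c_np), c_fc = as.integer(c_fc),
         contrast_times = contrast_times, p_cut = p_cut, lfc_cut = lfc_cut,
         term_config = term_config),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] may be set in the file; unset fields
#' keep their defaults.  `seed` is mandatory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) abort("config file must set `seed`.")
  allowed <- c("seed", "times", "n_replicates", "strains", "m", "c_np",
               "c_fc", "contrast_times", "p_cut", "lfc_cut")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config field: %s", unknown[1L]))
  }
  do.call(pipeline_config, raw)
}

write_stage_tsv <- function(x, path, config_hash, stage) {
  writeLines(sprintf("# timefuzz %s | config %s", stage, config_hash), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  path
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates the two-strain time course, builds the normalized-profile (NP)
#' and fold-change (FC) views, tests producer-versus-control contrasts with
#' the moderated t, clusters both views with fuzzy c-means, cross-tabulates
#' the two clusterings, and tests the planted annotation terms for
#' over-representation in the NP clusters.  Every table is written under
#' `out_dir` with a header comment naming the stage and a configuration
#' hash; a run log records seeds and parameters.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#'
#' @return Invisibly, a list with the in-memory stage results and the output
#'   file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- substr(rlang::hash(unclass(config)), 1L, 12L)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    inform(line)
  }
  logf("run start | seed %d | config %s", config$seed, hash)

  sim <- simulate_timecourse(config$sim)
  paths <- list()
  paths$values <- file.path(out_dir, "expression.tsv")
  paths$metadata <- file.path(out_dir, "samples.tsv")
  write_expression_tsv(sim$expression, paths$values, paths$metadata)
  paths$truth <- write_stage_tsv(sim$truth,
                                 file.path(out_dir, "truth_archetypes.tsv"),
                                 hash, "simulate")
  logf("simulated %d genes x %d samples",
       nrow(sim$truth), dplyr::n_distinct(sim$expression$sample))

  avg <- average_replicates(sim$expression)
  np <- normalized_profiles(avg, strains = config$sim$strains)
  fc <- fold_change_profiles(avg, producer = config$sim$strains[1L],
                             control = config$sim$strains[2L])
  paths$np <- file.path(out_dir, "profiles_np.tsv")
  paths$fc <- file.path(out_dir, "profiles_fc.tsv")
  write_profile_tsv(np, paths$np)
  write_profile_tsv(fc, paths$fc)

  contrasts <- lapply(config$contrast_times, function(t) {
    sprintf("%s_%g", config$sim$strains, t)
  })
  de <- moderated_de(sim$expression, contrasts)
  paths$de <- write_stage_tsv(de, file.path(out_dir, "diffexpr.tsv"),
                              hash, "de")
  prior <- attr(de, "prior")
  logf("moderated t: prior df %.3g, prior variance %.4g",
       prior$df_prior, prior$var_prior)

  fit_np <- fcm_fit(np, centers = config$c_np, m = config$m,
                    seed = stage_seed(config$seed, 11L))
  fit_fc <- fcm_fit(fc, centers = config$c_fc, m = config$m,
                    seed = stage_seed(config$seed, 12L))
  paths$np_membership <- write_stage_tsv(
    tidy(fit_np), file.path(out_dir, "memberships_np.tsv"), hash, "cluster-np")
  paths$fc_membership <- write_stage_tsv(
    tidy(fit_fc), file.path(out_dir, "memberships_fc.tsv"), hash, "cluster-fc")
  logf("clustered NP (c=%d) and FC (c=%d) at m=%.3g",
       config$c_np, config$c_fc, config$m)

  cont <- compare_clusterings(fit_np, fit_fc)
  paths$contingency <- write_stage_tsv(
    tidy(cont), file.path(out_dir, "contingency_np_fc.tsv"), hash, "compare")

  terms <- simulate_term_map(config$sim, sim$truth,
                             term_config = config$term_config)
  paths$gmt <- file.path(out_dir, "terms.gmt")
  write_gmt(terms, paths$gmt)
  enr <- enrich_clusters(hard_assignments(fit_np), terms,
                         universe = sim$truth$gene)
  paths$enrichment <- write_stage_tsv(
    enr, file.path(out_dir, "enrichment_np.tsv"), hash, "enrich")
  logf("run complete: %d output files", length(paths))

  invisible(list(
    sim = sim, np = np, fc = fc, de = de, fit_np = fit_np, fit_fc = fit_fc,
    contingency = cont, terms = terms, enrichment = enr, paths = paths
  ))
}
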