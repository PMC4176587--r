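#' Fit per-gene one-way group-means models
#'
#' Each gene is modelled by least squares in a one-way layout: one mean per
#' experimental condition (group), with a pooled residual variance across
#' all conditions.  Groups default to the combination of strain and time.
#'
#' @param expr Long expression tibble with columns `gene`, `sample`, `value`
#'   plus the grouping columns.
#' @param group_cols Metadata columns combined (with `_`) into the per-sample
#'   group label; default `c("strain", "time_h")`.
#'
#' @return Object of class `de_fit`: list with `means` (gene x group),
#'   `s2` (pooled residual variance per gene), `df` (residual degrees of
#'   freedom, samples minus groups), `n_per_group`, `groups` (per-sample
#'   labels).
#' @export
fit_models <- function(expr, group_cols = c("strain", "time_h")) {
  if (!all(c("gene", "sample", "value") %in% names(expr))) {
    abort("`expr` needs columns gene, sample, value.")
  }
  if (!all(group_cols %in% names(expr))) {
    abort("grouping columns missing from `expr`.")
  }
  y <- expression_matrix(expr)
  meta <- dplyr::distinct(expr, dplyr::across(dplyr::all_of(c("sample", group_cols))))
  meta <- meta[match(colnames(y), meta$sample), ]
  lab <- do.call(paste, c(meta[group_cols], sep = "_"))
  f <- factor(lab, levels = unique(lab))
  n_per <- table(f)
  df <- ncol(y) - nlevels(f)
  if (df <= 0L) abort("no residual degrees of freedom (df <= 0).")

  ind <- stats::model.matrix(~ 0 + f)
  means <- y %*% ind %*% diag(1 / as.numeric(n_per), nlevels(f))
  colnames(means) <- levels(f)
  rss <- rowSums(y^2) - colSums(t(means^2) * as.numeric(n_per))
  s2 <- pmax(rss, 0) / df

  structure(
    list(means = means, s2 = setNames(s2, rownames(y)), df = df,
         n_per_group = setNames(as.integer(n_per), levels(f)),
         groups = setNames(lab, colnames(y))),
    class = "de_fit"
  )
}

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(x) = y` for `x > 0`, to a relative
#' tolerance of 1e-8.  Used by the empirical-Bayes hyperparameter
#' moment-matching.
#'
#' @param y Positive numeric vector.
#' @return `x` with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(NaN)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (-dif / x < 1e-8) break
    }
    x
  }, double(1))
}

#' Estimate the variance-prior hyperparameters
#'
#' Moment-matching on the marginal distribution of log residual variances:
#' the model takes per-gene true variances as scaled inverse chi-square with
#' `df_prior` degrees of freedom and scale `var_prior`, so that
#' `log(s2)` has known digamma/trigamma moments.  `df_prior` above 1e6 is
#' reported as infinite (the log-variances are underdispersed relative to
#' pure sampling noise).
#'
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom (scalar or per-gene vector).
#'
#' @return List with `df_prior` and `var_prior`.
#' @export
estimate_variance_prior <- function(s2, df) {
  df <- rep(df, length.out = length(s2))
  pos <- s2 > 0 & is.finite(s2) & df > 0
  if (!any(pos)) abort("degenerate ensemble: no positive residual variances.")
  if (sum(pos) < 10L) {
    warn("fewer than 10 informative genes; hyperparameter estimates are unstable.")
  }
  s2 <- s2[pos]
  df <- df[pos]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  n <- length(e)
  e_bar <- mean(e)
  target <- mean((e - e_bar)^2 * n / (n - 1) - trigamma(df / 2))
  if (target > 0) {
    df_prior <- 2 * trigamma_inverse(target)
    if (df_prior > 1e6) df_prior <- Inf
  } else {
    df_prior <- Inf
  }
  var_prior <- if (is.finite(df_prior)) {
    exp(e_bar + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    exp(e_bar)
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Moderated t-statistics for condition contrasts
#'
#' Shrinks each gene's residual variance toward the empirical-Bayes prior:
#' the posterior variance is
#' `(d0 * s0^2 + df * s2) / (d0 + df)`, the moderated t for contrast A - B is
#' the coefficient difference over `s_post * sqrt(1/nA + 1/nB)`, and
#' two-sided p-values use a t distribution on `d0 + df` degrees of freedom.
#' With `prior_df = 0` this reduces to the ordinary pooled-variance t; with
#' `prior_df = Inf` every posterior variance equals the prior variance.
#'
#' @param fit A [fit_models()] object.
#' @param contrasts A length-2 character vector `c(A, B)` or a list of such
#'   vectors; each names two groups of the fit.
#' @param prior_df,prior_var Optional hyperparameter overrides; estimated
#'   from the data via [estimate_variance_prior()] when `NULL`.
#'
#' @return Tibble with columns `gene`, `contrast`, `log2fc`, `t_mod`,
#'   `df_total`, `p_raw`; hyperparameters in the `prior` attribute.  No
#'   multiple-testing adjustment is applied here (see [adjust_bh()]).
#' @export
moderate <- function(fit, contrasts, prior_df = NULL, prior_var = NULL) {
  stopifnot(inherits(fit, "de_fit"))
  if (is.character(contrasts)) contrasts <- list(contrasts)
  lv <- colnames(fit$means)
  for (ct in contrasts) {
    if (length(ct) != 2L || !all(ct %in% lv)) {
      abort(sprintf("contrast must name two of: %s", paste(lv, collapse = ", ")))
    }
  }
  if (is.null(prior_df)) {
    if (all(fit$s2 == fit$s2[1L]) && fit$s2[1L] == 0) {
      abort("degenerate ensemble: all residual variances are zero.")
    }
    prior <- estimate_variance_prior(fit$s2, fit$df)
  } else {
    prior <- list(df_prior = prior_df,
                  var_prior = prior_var %||%
                    estimate_variance_prior(fit$s2, fit$df)$var_prior)
  }
  d0 <- prior$df_prior
  s0 <- prior$var_prior
  s2_post <- if (is.infinite(d0)) {
    rep(s0, length(fit$s2))
  } else if (d0 == 0) {
    fit$s2
  } else {
    (d0 * s0 + fit$df * fit$s2) / (d0 + fit$df)
  }
  df_total <- d0 + fit$df

  out <- lapply(contrasts, function(ct) {
    na <- fit$n_per_group[[ct[1L]]]
    nb <- fit$n_per_group[[ct[2L]]]
    if (na < 2L || nb < 2L) {
      abort(sprintf("contrast %s vs %s: both groups need >= 2 samples.",
                    ct[1L], ct[2L]))
    }
    lfc <- fit$means[, ct[1L]] - fit$means[, ct[2L]]
    se <- sqrt(s2_post * (1 / na + 1 / nb))
    t_mod <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
    tibble(
      gene = rownames(fit$means),
      contrast = paste(ct[1L], "vs", ct[2L]),
      log2fc = unname(lfc),
      t_mod = unname(t_mod),
      df_total = df_total,
      p_raw = 2 * pt(abs(t_mod), df = df_total, lower.tail = FALSE)
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "prior") <- prior
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone step-up, capped at 1), in the input
#'   order; elementwise at least the raw p-values.
#' @export
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
adjust_bh <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("`p` must be numeric in [0, 1] without missing values.")
  }
  p.adjust(p, method = "BH")
}

#' Moderated differential expression in one call
#'
#' Convenience wrapper: [fit_models()], [moderate()], then [adjust_bh()]
#' applied per contrast.
#'
#' @inheritParams fit_models
#' @inheritParams moderate
#' @return The [moderate()] tibble with an added `p_adj` column.
#' @export
moderated_de <- function(expr, contrasts, group_cols = c("strain", "time_h"),
                         prior_df = NULL, prior_var = NULL) {
  fit <- fit_models(expr, group_cols = group_cols)
  de <- moderate(fit, contrasts, prior_df = prior_df, prior_var = prior_var)
  prior <- attr(de, "prior")
  de <- dplyr::mutate(dplyr::group_by(de, .data$contrast),
                      p_adj = adjust_bh(.data$p_raw))
  de <- dplyr::ungroup(de)
  attr(de, "prior") <- prior
  de
}

#' Select significantly changed genes
#'
#' A gene passes for a contrast when its (adjusted) p-value is below `p_cut`
#' and its absolute log2 fold change reaches `lfc_cut`.  Defaults mirror a
#' stringent microarray screen: `p_cut = 1e-05` on the BH-adjusted p-value
#' and `lfc_cut = 1` (2-fold).
#'
#' @param de A [moderated_de()] result (needs `p_adj` unless
#'   `adjusted = FALSE`).
#' @param p_cut P-value cut-off.
#' @param lfc_cut Absolute log2-fold-change cut-off.
#' @param adjusted Apply `p_cut` to BH-adjusted (default) or raw p-values.
#'
#' @return The selected rows of `de`.
#' @export
select_significant <- function(de, p_cut = 1e-05, lfc_cut = 1,
                               adjusted = TRUE) {
  pcol <- if (adjusted) "p_adj" else "p_raw"
  if (!pcol %in% names(de)) {
    abort(sprintf("`de` lacks a %s column.", pcol))
  }
  dplyr::filter(de, .data[[pcol]] < p_cut, abs(.data$log2fc) >= lfc_cut)
}
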