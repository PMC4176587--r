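# timefuzz

Dual-view fuzzy c-means analysis of two-strain time-course expression data.

When an engineered production strain (for example a yeast secreting a weak
organic acid) is profiled against its isogenic control over a fermentation
time course, two complementary questions arise: *which temporal expression
shapes exist* and *where do the strains differ*. timefuzz implements the
full analysis chain for that design:

- **Two clustering views.** Normalized profiles (NP; per-gene trajectories
  z-scored to mean 0, sd 1, producer and control concatenated) capture
  profile *shape*; fold-change profiles (FC; per-time log2 producer/control
  ratios, −1 = 2-fold down, +1 = 2-fold up) capture *strain differences*.
- **Fuzzy c-means** with graded memberships, minimizing
  `J = Σ_g Σ_j u_gj^m ‖x_g − v_j‖²` with the classic alternating updates
  (`u_gj = 1/Σ_k (d_gj/d_gk)^{2/(m−1)}`), plus the two parameter-selection
  heuristics used in time-course microarray practice: the fuzziness
  exponent `m` is the smallest value that detects *no* clusters in
  row-randomized data, and the cluster count `c` is the largest value whose
  clusters are all anchored (≥ 1 gene with membership ≥ 0.5) and stable
  across repeated runs (matched-centroid correlation ≥ 0.9).
- **Moderated differential expression**: per-gene one-way least squares,
  empirical-Bayes variance shrinkage via moment matching on log variances
  (posterior variance `(d0·s0² + d_g·s²_g)/(d0 + d_g)`, moderated t on
  `d0 + d_g` df), Benjamini–Hochberg FDR, and the stringent
  `p_adj < 1e−5`, `|log2FC| ≥ 1` screen.
- **Cluster enrichment**: upper-tail hypergeometric tests of GMT term maps
  within hard-assigned clusters.
- **Cross-study integration**: quantile normalization, sign-preserving
  scaling of each study's log2 ratios to a common range (default
  `[−4.03, 4.07]`), selection of genes significant in ≥ 2 comparisons, and
  complete-linkage hierarchical clustering of both axes into an ordered
  heatmap matrix with newick dendrogram export.
- **A synthetic-data module** that generates all inputs with known ground
  truth: planted temporal archetypes (steady up/down, transient, delayed
  producer-specific induction, flat with strain offset), term maps with
  planted enrichment, and multi-study log2-ratio tables with shared
  response modules.

Everything is tidyverse-shaped: long tibbles in, tibbles out, `tidy()` /
`glance()` methods for fitted objects, `autoplot()` for clusters, volcano
plots and integrated heatmaps.

## Worked example

Simulate the default study design — 5 archetypes × 200 genes, 6 sampling
times (0–71 h), two strains × 3 cultures, 0.2 log2-units replicate noise —
then select `m`, cluster the NP view and test the planted term map:

```r
library(timefuzz)
library(dplyr)

cfg <- pipeline_config(seed = 1)
sim <- simulate_timecourse(cfg$sim)
np  <- normalized_profiles(average_replicates(sim$expression))

select_m(np, m_grid = c(1.15, 1.25, 1.35, 1.5), centers = 5, n_seeds = 3,
         seed = 1)
#> Selected fuzziness exponent m = 1.35 (c = 5 during screen)

fit <- fcm_fit(np, centers = 5, m = 1.35, seed = 1)
glance(fit)
#> # A tibble: 1 × 7
#>       c     m n_genes n_iter converged objective frac_high_membership
#>   <int> <dbl>   <int>  <int> <lgl>         <dbl>                <dbl>
#> 1     5  1.35    1000      3 TRUE           143.                    1
```

At `m = 1.35` the screen finds no structure in randomized data (fraction of
genes with membership ≥ 0.5 drops to 0, versus 0.80 at `m = 1.15`), while on
the real data every gene is crisply assigned. The hard assignments recover
the planted archetypes exactly (adjusted Rand index 1.0), and the planted
annotation terms dominate the enrichment table of their clusters:

```r
terms <- simulate_term_map(cfg$sim, sim$truth)
enrich_clusters(hard_assignments(fit), terms, universe = sim$truth$gene) |>
  head(3)
#> # A tibble: 3 × 8
#>   cluster term            k     K     n     N    p_raw    p_adj
#>   <chr>   <chr>       <int> <int> <int> <int>    <dbl>    <dbl>
#> 1 c1      T_up           60    60   200  1000 3.57e-46 1.43e-45
#> 2 c2      T_transient    60    70   200  1000 2.88e-35 1.15e-34
#> 3 c5      T_delayed      60    80   200  1000 5.13e-29 2.05e-28
```

Here `k`/`K` are the term genes inside/everywhere, `n` the cluster size, `N`
the measured universe; `p_raw` is the upper-tail hypergeometric probability
of an overlap at least that large by chance.

Differential expression at 47 h flags the strain-affected archetypes:

```r
de <- moderated_de(sim$expression, list(c("producer_47", "control_47")))
select_significant(de) |> arrange(p_adj) |> head(3)
#> # A tibble: 3 × 7
#>   gene   contrast                  log2fc t_mod df_total    p_raw    p_adj
#>   <chr>  <chr>                      <dbl> <dbl>    <dbl>    <dbl>    <dbl>
#> 1 g00966 producer_47 vs control_47   1.91  11.6      Inf 2.61e-31 2.61e-28
#> 2 g00979 producer_47 vs control_47   1.86  11.3      Inf 8.78e-30 4.39e-27
#> 3 g00856 producer_47 vs control_47   1.84  11.2      Inf 2.70e-29 7.60e-27
```

(`df_total = Inf` because in this homoscedastic simulation the log-variances
are underdispersed and the prior degrees of freedom are estimated as
infinite — full shrinkage to the common variance.)

`run_pipeline(cfg, out_dir)` executes the whole chain — simulate,
preprocess, DE, NP and FC clustering, NP×FC contingency, enrichment — and
writes every stage as TSV (plus GMT terms and a run log) with a config-hash
header, reproducibly from the single seed.

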