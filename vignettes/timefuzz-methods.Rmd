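---
title: "Dual-view soft clustering of time-course expression data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-view soft clustering of time-course expression data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timefuzz)
library(dplyr)
```

timefuzz analyses two-strain time-course expression experiments of the kind
used to study metabolically engineered yeast: a producer strain (for example
one secreting a weak organic acid such as D-xylonate) and an isogenic
control, sampled at a handful of time points with a few independent cultures
each. The package covers the full analysis chain — soft clustering of
temporal profiles in two complementary views, moderated differential
expression, cluster enrichment, and integration of log2-ratio tables across
published studies — together with a synthetic-data module that generates
every input with known ground truth.

## The two clustering views

Replicates are averaged per (strain, time) cell before profile construction;
replicate variability is handled separately by the moderated t machinery, so
clustering sees one trajectory per gene and strain.

**Normalized profiles (NP)** emphasize the *shape* of a trajectory: each
gene's values are centred to mean 0 and scaled to standard deviation 1
(sample sd, $n-1$ denominator). Zero-variance rows cannot be scaled; they
are flagged degenerate and excluded from clustering input but retained in a
reported exclusion list. No other gene filtering is applied before
clustering. By default the producer and control trajectories are
concatenated and scaled as one vector, so each NP profile shows both
strains' shapes at once and strain-specific induction becomes part of the
shape; `normalized_profiles(strains =)` switches to per-strain scaling when
single-strain shape is wanted. We prefer the concatenated default because it
lets one clustering display both strains per cluster panel.

**Fold-change profiles (FC)** emphasize *strain differences*: per gene and
time, the producer's mean log2 intensity minus the control's. The log2
ratio gives up- and down-regulation equal weight: $-1$ is 2-fold down and
$+1$ is 2-fold up in the producer. No row scaling is applied.

## Fuzzy c-means and its two tuning parameters

Both views are clustered with fuzzy c-means, which minimizes

$$J = \sum_g \sum_{j=1}^{c} u_{gj}^m \, \lVert x_g - v_j \rVert^2,$$

by alternating the membership update
$u_{gj} = 1 / \sum_k (d_{gj}/d_{gk})^{2/(m-1)}$ and the weighted centroid
update. Memberships are graded in $[0,1]$ and sum to 1 per gene. A gene that
coincides with a centroid receives membership 1 there (split equally over
coinciding centroids) — the exact-hit rule. Convergence is declared when the
maximum absolute membership change drops below `tol` (default `1e-6`, a
bounded scale independent of data magnitude) or after `max_iter = 500`
iterations.

**Initialization and the soft warm start.** Memberships are initialized
uniform-random (row-normalized) from the user's seed, so runs are exactly
reproducible. Random-membership initialization places every initial
centroid at the grand mean, and at the near-hard operating exponents used
here ($m \approx 1.35$) the alternation then visits local optima often
enough to disturb downstream parameter selection. `fcm_fit()` therefore uses
a deterministic-annealing-style continuation: when the target $m < 2$, the
alternation first runs at $m = 2$ to a loose tolerance (`1e-3`, at most 100
iterations) and the resulting memberships initialize the target-$m$ run. The
soft phase has a strong global pull toward dense regions (and a single
collapsed optimum on structureless data), which removes almost all local
optima of the crisp objective while leaving the fitted stationary points
unchanged. The recorded `objective_trace` covers the target-$m$ phase only
and is non-increasing at every iteration, which the test suite asserts on
random data.

**Choosing the fuzziness exponent `m`** (`select_m()`). The exponent
controls noise sensitivity: $m \to 1$ approaches hard k-means and will
crisply partition anything, while large $m$ flattens memberships toward
$1/c$. The screen runs the clustering on row-permuted (structureless)
versions of the data over several seeds and declares "clusters detected"
when more than `detection_frac = 1%` of genes reach membership 0.5 — the
same 0.5 anchor used everywhere else. The chosen `m` is the smallest grid
value that stays quiet on every randomized run: the softest setting that
refuses to invent structure in noise. On the default study-scale synthetic
data (1,000 genes, 12 profile coordinates) the screen selects 1.35; the
quiet point moves with gene count, dimension and `c`, which is why the
screen is run per dataset rather than hard-coding the exponent.

**Choosing the cluster count `c`** (`select_c()`). A candidate passes when
(1) in repeated runs every cluster is *anchored* — contains at least one
gene with membership $\ge 0.5$ — and (2) runs from different seeds agree:
greedily best-matched centroid pairs all correlate at `stability_r = 0.9`
or better. Stability-by-correlation quantifies the visual "similar looking
clusters in repeated runs" judgement that cannot be tested directly. The
chosen `c` is the largest grid value passing both, i.e. the finest anchored,
reproducible partition. Three repeats per candidate are the default: with
the warm start, repeated fits at a supported `c` agree essentially always,
so three pairwise comparisons suffice to expose the unstable candidates.

**Comparing the views** (`compare_clusterings()`). Genes are hard-assigned
at membership $\ge 0.5$ (never forced; sub-threshold genes stay
unassigned), and the NP-by-FC contingency table counts shared genes, which
shows how time-effect clusters distribute over strain-difference clusters.

## Moderated differential expression

Each gene follows a one-way least-squares layout: one mean per experimental
condition, pooled residual variance $s^2_g$ on $d_g$ degrees of freedom.
Conditions are compared pairwise. The empirical-Bayes model takes true
variances as scaled inverse chi-square with hyperparameters $(d_0, s_0^2)$
estimated by moment matching on $\log s^2_g$ (digamma/trigamma identities;
the trigamma inverse is solved by Newton iteration to `1e-8`; $d_0$ above
`1e6` is reported infinite). The posterior variance
$\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$ gives the moderated t
on $d_0 + d_g$ degrees of freedom; p-values are two-sided throughout since
both directions of regulation are of interest. Setting `prior_df = 0`
recovers the ordinary pooled t, `prior_df = Inf` fully shrinks to the
prior — both limits are exercised in the tests, and the estimates are
cross-checked against the limma implementation of the same model.

Multiple testing uses the Benjamini–Hochberg step-up (`adjust_bh()`, a
validated wrapper over `p.adjust`); ties need no special casing because the
step-up minimum construction handles them. The default screen keeps genes
with adjusted $p < 10^{-5}$ and $|\log_2 \text{FC}| \ge 1$. The cut-off is
applied to the *adjusted* p-value by default — the BH correction exists
precisely to make that threshold interpretable — with `adjusted = FALSE`
available for raw-p screening.

## Cluster enrichment

Over-representation of annotation terms (GO-class- or pathway-style GMT
files) within hard-assigned clusters uses the plain upper-tail
hypergeometric test, computed in log space. This is a deliberate
simplification relative to ontology-aware conditional tests: no GO graph is
consulted, terms are independent gene sets. The universe is the measured
gene set (all genes on the matrix), not all annotated genes, matching how
the clusters were drawn. Raw p-values are primary output; BH-adjusted
values across the terms tested within each cluster are supplementary.
Terms with fewer than `min_term_size = 3` measured genes are skipped.

## Cross-study integration

Published comparisons arrive as per-study log2 ratios (case versus matched
control) with per-gene significance flags. Harmonization proceeds in the
order: quantile normalization for studies with full data (columns with
missing genes bypass it), then scaling of every study to a common range,
by default $[-4.03, 4.07]$. The range map is sign-preserving and
piecewise-linear through zero — positive values are multiplied by
$\mathrm{hi}/\max(x)$, negative by $\mathrm{lo}/\min(x)$ — because an
affine min-max map would shift the zero point of a log2 ratio and corrupt
its up/down meaning. The map is monotone, so within-study gene ranking is
untouched; the exact transform behind a published common range is rarely
stated, and this choice is the one that preserves ratio semantics. Genes
flagged significant in at least `min_count = 2` comparisons are retained,
and both axes are ordered by complete-linkage hierarchical clustering on
Euclidean distances (merge heights are non-decreasing, the ultrametric
property asserted in the tests). Genes missing from a study contribute 0 to
clustering distances after a logged warning and render as missing in the
export. Alternative selection predicates (for example fold-change-based
rules against a time-zero reference) are expressed by preparing the
`significant` flags accordingly before `build_heatmap_matrix()`.

A caution learned from the tie structure of quantile normalization: with
(near-)zero-noise columns, massive ties make normalized columns nearly
constant, and distances between them lose meaning. Real log2-ratio tables
are continuous, so this arises only in degenerate synthetic settings.

## The synthetic-data module

The simulator emulates the study design end to end: two strains, six
sampling times (0, 7, 23, 47, 49, 71 h), three independent cultures per
strain, and genes drawn from temporal archetypes with additive Gaussian
noise on the log2 scale (noise is additive in log2 space because that is
the scale on which normalized intensities are analysed). The default
archetype set has five shapes of 200 genes each: steady up-regulation,
steady down-regulation, a transient pulse, a producer-specific delayed
induction, and a flat trajectory with a constant producer offset. The last
two carry strain effects so that every archetype has a distinct
concatenated-strain NP shape — modelling strain-specific induction and
constitutive strain differences, both expected in an engineered-producer
comparison. The replicate noise default of 0.2 log2 units is the package's
choice of a realistic microarray replicate scatter; it is not a published
value.

Ground truth (gene-to-archetype, term membership, module definitions) is
always returned alongside the data, never encoded in identifiers, so tests
cannot leak labels. All generators are pure functions of (configuration,
seed); `permute_matrix()` implements the row-wise randomization used by the
`m` screen, preserving each gene's value multiset while destroying temporal
structure.

What the simulator does *not* emulate: probe-level effects, dye or batch
effects, intensity-dependent variance, correlated replicate structure, or
missing values. Passing the planted-recovery tests therefore demonstrates
the correctness of the machinery under the stated noise model, not
performance on raw array data, which additionally depends on upstream
normalization quality.

## Problem sizes and numerical choices

The test suite and the acceptance script work at the study scale the
simulator defaults encode: 1,000 genes in 12 profile coordinates for
clustering (10 seeds for recovery, 20 trials for `c` selection), 2,000
genes for null calibration, 5,000 genes for hyperparameter recovery, and 20
studies of 1,000 genes for integration (20 seeds). These sizes make every
property estimable in minutes on one core while keeping the planted-signal
geometry identical to larger runs.

Numerical details worth knowing: squared distances are floored at 0 before
the membership update; an exact centroid hit short-circuits to a one-hot
membership; duplicate initial centroids trigger a re-draw; all-zero inputs
to the range scaler return unchanged with a warning; BH inputs outside
$[0,1]$ and inconsistent hypergeometric counts are rejected rather than
clamped.

## Limitations

- The one-way layout covers paired-condition contrasts only; factorial
  designs, array weights and duplicate-probe correlation are out of scope.
- Enrichment ignores the ontology graph; strongly overlapping terms will
  co-fire.
- The integration step's common-range scaling intentionally discards
  absolute fold-change magnitude across studies; only signs and
  within-study order are preserved.
- `select_c()` reports the largest stable anchored `c`; on data with nested
  structure several candidates can pass, and the diagnostics table should
  be inspected rather than trusting the single returned value blindly.

## A worked mini-run

```{r mini-run}
cfg <- pipeline_config(seed = 1)
sim <- simulate_timecourse(cfg$sim)
np <- normalized_profiles(average_replicates(sim$expression))
fit <- fcm_fit(np, centers = 5, m = 1.35, seed = 1)
glance(fit)

ha <- hard_assignments(fit)
joined <- inner_join(ha, sim$truth, by = "gene")
adjusted_rand_index(joined$cluster, joined$archetype)
```

```{r centroids, fig.width = 7, fig.height = 4}
autoplot(fit)
```
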