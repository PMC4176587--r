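Package: timefuzz
Title: Dual-View Fuzzy C-Means Analysis of Time-Course Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Soft clustering of two-strain time-course gene expression
    experiments with fuzzy c-means, including randomization-based selection of
    the fuzziness exponent, membership- and stability-based selection of the
    cluster number, and cross-tabulation of clusterings built from normalized
    profiles versus fold-change profiles.  Also provides moderated
    differential-expression testing with empirical-Bayes variance shrinkage,
    hypergeometric over-representation testing of annotation terms within
    clusters, and cross-study integration of log2-ratio tables by quantile
    normalization, sign-preserving range scaling, recurrent-significance gene
    selection and complete-linkage hierarchical clustering.  A synthetic-data
    module generates expression matrices with planted temporal archetypes,
    term maps and multi-study ratio tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
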