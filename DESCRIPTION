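Package: scztype
Title: Transcriptomic Subtyping of Schizophrenia Cases Across Bulk RNA-seq Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Splits schizophrenia cases into transcriptomic subtypes (Type 1,
    Type 2, Mix) across multiple overlapping bulk RNA-seq cohorts and scores
    neuroinflammation gene panels per subtype. Provides a negative-binomial
    multi-cohort simulator with planted subtype structure, count filtering and
    variance-stabilizing transformation, precision-weighted per-gene linear
    models with empirical-Bayes moderation and Benjamini-Hochberg correction,
    two-group k-means subtype discovery with a DE-count labeling rule,
    cross-cohort consensus classification of shared subjects, and gene-panel
    log-fold-change statistics with one-way ANOVA and Tukey HSD comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    MASS,
    ggplot2,
    Matrix,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
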