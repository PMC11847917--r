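Package: panAgeScreen
Title: Pan-Tissue Age-Correlation Screening for Transcriptomic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tissue-agnostic screen for genes whose expression tracks
    chronological age across a multi-tissue RNA-seq cohort. Counts are
    normalized by median-of-ratios size factors and a variance-stabilizing
    log transform, categorical batch structure (sex, anatomical subsite) is
    residualized by a linear model that protects the age covariate, and each
    tissue is screened with a Leave-Half-Out resampled Spearman correlation
    between expression and donor age, with a per-gene 3-SD outlier exclusion
    inside every resampling fold. Per-tissue estimates are averaged across
    tissues to rank genes by tissue-independent association with age, and
    significance is assessed by donor-age permutation tests. A parallel
    Pearson correlation path with Benjamini-Hochberg adjustment, a
    MAD-scaled sample-quality statistic for pairwise correlation profiles,
    and a seeded negative-binomial multi-tissue cohort simulator for
    end-to-end validation are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    matrixStats,
    S4Vectors,
    SummarizedExperiment,
    limma,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
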