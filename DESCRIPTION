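Package: boomics
Title: Multi-Omic Characterization of Bladder Outlet Obstruction Before and After De-Obstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired transcriptome and proteome profiling of
    bladder-outlet-obstruction patients before and after surgical de-obstruction.
    Provides urodynamic index calculation (BCI, BOOI) and pressure-group assignment,
    two negative-binomial differential-expression procedures with dual-method
    consensus and before/after bookkeeping, PCA loading-range selection of
    classifier genes, label-free proteomics differential expression with two-tier
    left-censored imputation, a moderated t-test, significance curves and repeated
    imputation consistency flags, hypergeometric GO over-representation with
    Resnik semantic-similarity pruning and binary-cut clustering, transcription
    factor regulon trajectory analysis, and synthetic-data generators that emulate
    the study design for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    cluster
Suggests:
    testthat (>= 3.0.0),
    limma,
    DESeq2,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
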