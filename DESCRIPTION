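Package: sslrna
Title: Skin-Surface-Lipid RNA Profiling and Disease Discrimination Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible analysis pipeline for targeted RNA-seq read-count
    profiles obtained from skin surface lipids (SSL-RNA), aimed at
    discriminating Parkinson's disease from healthy controls. Provides a
    seeded negative-binomial cohort simulator with planted differential
    signal and quality-failure samples, sample- and gene-level QC filters,
    median-of-ratios size-factor normalization with a variance-stabilizing
    log transform and top-variance PCA, per-gene negative-binomial
    likelihood-ratio differential-expression tests with
    Benjamini-Hochberg FDR control, and a stacked machine-learning model in
    which an extremely-randomized-trees Hoehn & Yahr stage regressor feeds a
    disease classifier built on rank-normalized expression features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    DESeq2,
    optparse
Config/testthat/edition: 3
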