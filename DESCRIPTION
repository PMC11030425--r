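Package: vgRecal
Title: Recalibrating Differential Expression Fold Changes by Population
    Genetic Dosage Variance
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rescales differential-expression log fold changes by the
    standard deviation of a gene's population genetic dosage variance
    (V^G), so that expression changes are measured in units of natural
    population variability rather than nominal magnitude. Provides the
    V^G algebra (TPM-weighted harmonic-mean tissue aggregation, score
    merging with allelic-expression precedence, log-base conversion),
    recalibration and re-ranking of DESeq2-style result tables,
    gene-set distribution comparisons, native hypergeometric
    over-representation analysis with before/after enrichment
    comparison, a gradient-boosted model that extends V^G to genes
    lacking allelic-expression estimates (with K-nearest-neighbour
    feature imputation), a synthetic-data generator with planted
    driver/responder structure for end-to-end testing, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Transcriptomics, DifferentialExpression, GeneExpression,
    GeneSetEnrichment, MachineLearning
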