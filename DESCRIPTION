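Package: heritvar
Title: Multigenerational Analysis of Environment-Induced Heritable Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing multigenerational
    common-garden experiments that test whether ancestral environments induce
    heritable phenotypic and gene-expression changes. Provides constructors
    for single-seed-descent designs with randomized growth-room layouts,
    genotype-specific effect-size estimation from linear mixed models,
    classification of induced changes as transient, heritable or persistent
    across offspring generations, occurrence modelling with binomial mixed
    models and single-step multiple-comparison adjustment, regression of
    occurrence frequency on climate, methylation and transposon abundance,
    a negative-binomial Wald test for differential expression with a
    heritable-DEG rule, and a resampling test for transposon enrichment in
    the 2 kb upstream and gene-body regions of susceptible genes. Synthetic
    generators with planted ground truth support parameter-recovery and
    calibration studies of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    lme4,
    car,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
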