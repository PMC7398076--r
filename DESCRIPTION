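Package: sparseDA
Title: Benchmarking Differential Abundance Methods on Sparse Microbiome Counts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A benchmarking framework for differential abundance (DA)
    analysis of sparse feature-by-sample count tables from 16S amplicon and
    whole metagenome shotgun (WMS) sequencing. Provides goodness-of-fit
    diagnostics for five count models (negative binomial, zero-inflated
    negative binomial, zero-inflated Gaussian, truncated Gaussian hurdle,
    Dirichlet-multinomial), a catalogue of DA methods behind a uniform
    interface, type I error evaluation on mock two-group splits, concordance
    at the top (CAT) analysis within and between methods, directional
    enrichment scoring against taxon metabolism annotations, and a parametric
    NB/ZINB simulator with differential abundance injection (with or without
    compensation), sparsity effects and power evaluation, plus rank
    aggregation across evaluation criteria.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    matrixStats,
    edgeR,
    limma,
    DESeq2,
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, DifferentialExpression, Software
RoxygenNote: 7.3.3
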