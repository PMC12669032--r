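Package: XenoScreen
Title: Growth Screening and Fitness Analysis of Chemical-Microbe Interactions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput chemical-bacteria growth
    screens and their genetic follow-up experiments. Turns plate-reader OD600
    time series into area-under-curve fitness proxies, normalizes plates
    against vehicle controls or row/column medians, calls compound-strain
    inhibition hits with a replicate-concordance rule, and determines minimum
    inhibitory concentrations. Includes per-gene fitness analysis of pooled
    barcoded transposon libraries (trimmed-mean normalization, permutation
    resampling, doublings correction, pathway enrichment), conditional-growth
    testing for arrayed mutant libraries, Tanimoto chemical-space coverage
    statistics, imbalance-aware random-forest classification of antibacterial
    activity, and community composition and bioaccumulation arithmetic. A
    synthetic-data generator with known ground truth makes every stage
    verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    ranger
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    pracma,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Microbiome, Genetics, Classification, Software
RoxygenNote: 7.3.3
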