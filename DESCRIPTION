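Package: chromeq
Title: Equalized Chromatin-State Modeling and Differential Occupancy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-condition chromatin-state and differential-occupancy analysis
    for binned epigenomic signal tracks. Provides equalized binarization of
    binned ChIP/ATAC signal so both conditions carry the same number of
    present calls per feature per chromosome, a multivariate
    Bernoulli-emission hidden Markov model trained jointly on both conditions
    with quantitative selection of the number of states, per-bp and per-bin
    fold-enrichment and hypergeometric statistics over genomic intervals,
    windowed differential-abundance testing with loess MA normalization and
    moderated negative-binomial quasi-likelihood tests, a factor co-occupancy
    odds-ratio screen, promoter-proximal gene association utilities, and a
    synthetic-data generator with recorded ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    limma,
    yaml,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
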