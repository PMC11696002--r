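Package: stmgrn
Title: Peak Annotation, Motif Discovery and Regulatory Network Inference
    for STM ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of chromatin-immunoprecipitation
    sequencing data for the Arabidopsis KNOX transcription factor
    SHOOT MERISTEMLESS (STM): consensus peak filtering against control
    sets, nearest-locus peak assignment with a responsiveness-aware
    equidistance rule, promoter/gene-body location binning,
    TGAC/TGAT-core oligomer and dyad discovery with Bernoulli and
    Markov background models, position-weight-matrix scanning with
    exact score p-values, early/late transcriptional-response
    classification, and consensus discrete Bayesian gene-regulatory
    network inference (BDeu score, simulated annealing, edge-frequency
    thresholding). Ships a seeded synthetic-data generator that
    emulates every input the pipeline consumes, so the full analysis
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
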