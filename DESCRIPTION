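Package: chromarch
Title: Two-Condition Comparison of Multiscale Hi-C Chromatin Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Compares three-dimensional genome organization between two
    conditions from binned Hi-C contact data. Implements contact-matrix
    normalization (depth scaling, Knight-Ruiz balancing, observed/expected),
    matrix-level comparison statistics (distance-decay curves, log2
    differential maps, stratum-adjusted correlation, windowed structural
    similarity z-scores), A/B compartment calling with saddle-plot
    compartment strength and switch classification, insulation-score TAD
    and boundary detection with shift-tolerant consensus and differential
    domains, chromatin loop calling by density clustering with aggregate
    peak analysis and depth-matched differential loops, and enrichment
    statistics linking architecture changes to differential gene
    expression. Ships a synthetic-data generator that plants known
    compartments, TADs, loops and matched gene/histone-mark/DHS tracks so
    every stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
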