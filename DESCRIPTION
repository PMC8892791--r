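Package: insulatr
Title: Sparse Insulation Regression for Hi-C Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression models of chromatin insulation from binned Hi-C
    contact matrices. A sparse insulation model identifies topologically
    associating domain (TAD) borders and facilitators by L0-penalised
    best-subset regression of distance-corrected contact residuals on
    per-bin spanning indicators; a differential insulation model tests
    border-strength changes between two experiments through
    experiment-interaction terms; and a prediction insulation model, a
    Poisson log-linear fit of counts on distance and insulation variables,
    predicts contact maps after chromosomal deletions and inversions.
    Includes ICE matrix balancing, the classical insulation score, a
    synthetic Hi-C generator with planted borders used as ground truth,
    interval-enrichment utilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    mgcv,
    glmnet,
    Rcpp,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    optparse,
    sandwich,
    lmtest,
    withr,
    stats,
    utils,
    graphics,
    grDevices,
    methods
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
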