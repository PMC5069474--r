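Package: mlphvg
Title: Multiscale Limited Penetrable Horizontal Visibility Graphs for
    Nonlinear Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Maps univariate time series onto complex networks with the
    multiscale limited penetrable horizontal visibility graph (MLPHVG)
    method: non-overlapping coarse-graining across temporal scales,
    horizontal visibility graphs that tolerate up to L penetrated
    (blocking) samples per link, and clustering-based network statistics
    (average clustering coefficient and clustering coefficient entropy)
    assembled into per-scale feature vectors. Includes seed-deterministic
    synthetic signal generators (i.i.d. noise, periodic, autoregressive,
    chaotic logistic map, and a two-class surrogate for healthy-versus-ictal
    EEG segments), leave-one-out and repeated stratified k-fold
    cross-validation with a support vector machine, and a command-line
    pipeline for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
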