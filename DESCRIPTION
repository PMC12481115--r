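Package: emgsynergy
Title: Muscle Synergy Extraction, Clustering and Developmental
    Fractionation Analysis for Multi-Channel Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for modular analysis of multi-channel surface
    electromyography (EMG): envelope preprocessing (Butterworth
    filtering, rectification, time normalization, amplitude
    scaling), non-negative matrix factorization with multi-restart
    optimization and variance-accounted-for (VAF) model-order
    selection, gap-statistic hierarchical clustering of synergy
    weight vectors, between-group centroid matching by scalar
    product, Hoyer sparseness quantification, and detection of
    fractionated or merged synergies via non-negative least
    squares. Includes a synthetic EMG generator with known modular
    ground truth for parameter-recovery validation, and
    Mann-Whitney / Cohen's d group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    pracma,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
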