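Package: collarcnn
Title: Cattle Behaviour Classification from Collar Accelerometers with
    Prunable 1D Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for classifying cattle behaviour states
    (rumination, eating, other) from 10 Hz neck-collar accelerometer
    streams. Provides readers for merged collar/halter CSV data, first-order
    differencing to remove gravity offsets from rotating collars, fixed-length
    windowing with majority-vote labelling, animal-grouped cross-validation,
    a compact one-dimensional convolutional network trained with AdamW and a
    one-cycle learning-rate policy, multi-stage structured filter pruning
    driven by an l1-norm importance ranking and a cubic sparsity schedule,
    half-precision weight reduction, and deployment accounting (parameter
    counts, multiply-accumulate operations, memory footprint, CPU cycles and
    duty-cycled battery lifetime) for low-power micro-controllers. A
    semi-Markov herd simulator generates labelled synthetic traces so every
    stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
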