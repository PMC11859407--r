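Package: myointent
Title: Myoelectric Intent Classification and Simulated Rehabilitation-Robot Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, fully simulatable pipeline for surface-electromyography
    (sEMG) driven control of an end-effector upper-limb rehabilitation robot.
    Generates labeled synthetic multi-channel sEMG emulating an isometric
    contraction protocol; conditions it with the standard band-pass/notch/
    rectification/envelope/MVC-normalization chain; classifies nine movement
    intents (rest plus eight planar directions) with single- and multi-stream
    one-dimensional convolutional networks trained by backpropagation; converts
    intents into virtual-force admittance commands for a simulated six-revolute-
    joint arm through a PD velocity controller with geometric-Jacobian inverse
    velocity solutions; and scores the resulting end-effector trajectories
    against standard test paths with smoothness, range-deviation and normalized
    path-length metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    Rcpp,
    yaml,
    jsonlite,
    withr,
    randomForest
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Matrix
Config/testthat/edition: 3
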