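Package: movefuse
Title: Fusion Classification of Multi-Axial Human Movement Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Feature-blind classification of segmented multi-axial wearable-sensor
    movement signals (e.g. accelerometer + gyroscope strike recordings) by fusing
    information across sensor axes at the input and output level. Provides four
    classifier input models (per-axis vectors, per-sensor matrices, a global
    inter-sensor matrix, and a sensor-stacked cuboid), one- to three-dimensional
    dynamic time warping with template classifiers, four convolutional network
    fusion classifiers trained by backpropagation, a synthetic multi-axial
    movement simulator with monotone time warps and latency jitter, and a
    repeated stratified holdout evaluation protocol with uniaxial baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
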