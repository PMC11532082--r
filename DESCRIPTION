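Package: neurofuse
Title: Multi-Level Feature Fusion for Neuronal Morphology Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for classifying neurons from their digital reconstructions.
    Reads and validates SWC morphology files, computes a 43-metric L-Measure-style
    morphometric vector, renders PCA-normalized orthogonal projection images, and
    trains a dual-branch fusion network in which a fully connected branch (over the
    morphometrics) and a convolutional branch (over the projections) exchange
    information through channel-attention feature enhancement and cross-attention
    feature interaction modules at several depths. Includes a synthetic neuron
    generator with class-dependent branching statistics, stratified k-fold
    cross-validation, and broom-style tidiers and ggplot2 autoplot methods for
    results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
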