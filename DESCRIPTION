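Package: pollensep
Title: Segmentation, Separation and Classification of Overlapping Pollen
    Grains in Light-Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end image analysis for stained airborne-pollen slides:
    CIELAB preprocessing, mean-shift colour clustering with Otsu
    binarization to isolate the pollen region, a Fibonacci-radius erosion
    schedule that detects overlapping grains, seed recovery by constrained
    dilation, grain separation with gradient-vector-flow active contours,
    a 33-dimensional shape/colour/texture descriptor per grain, and
    cross-validated multi-class evaluation (multilayer perceptron, random
    forest, naive Bayes) with confusion-matrix quality indicators.
    Includes a seeded synthetic-scene generator with per-grain ground
    truth so the whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    foreign,
    grDevices,
    jsonlite,
    nnet,
    png,
    ranger,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
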