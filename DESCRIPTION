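Package: spemix
Title: Open-Set Semi-Supervised Echocardiogram View Classification with
    Superclass Pseudo-Labels and Attention-Guided Mixup
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements SPEMix-style open-set semi-supervised training for
    echocardiogram view classification on single-channel images. A teacher
    network carries a dynamic-attention mixup block (DAMix) that learns a
    pixel-level mixing mask embedded with a Beta-distributed mixing ratio;
    a student network carries a superclass pseudo-label block (SP) that
    combines a close-set softmax classifier with one-vs-rest binary heads
    to score unlabeled images as in- or out-of-distribution and to assign
    every unlabeled image a (K+1)-way superclass pseudo-label. Teacher
    parameters track the student by exponential moving average. Includes a
    synthetic sector-fan ultrasound image generator with in- and
    out-of-distribution view classes, a compact re-parameterizable
    four-stage convolutional encoder, all loss terms, an end-to-end
    training loop, and confusion-matrix/ROC evaluation utilities. The
    network engine (layers, batch normalization, Adam, backpropagation) is
    implemented in R with C++ kernels for depthwise convolutions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    optparse
Config/testthat/edition: 3
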