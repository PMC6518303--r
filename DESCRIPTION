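Package: cbmir
Title: Classification-Based Medical Image Retrieval with a Modified Residual Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Content-based medical image retrieval (CBMIR) built on a deep
    residual convolutional network whose terminal 7x7 global average pooling is
    replaced by a learnable full-spatial convolution producing a 2048-dimensional
    feature vector. Provides the network builder with structural introspection
    (shape audit, residual-unit census), stochastic-gradient training with
    class-balance augmentation and transfer-learning layer freezing, a
    nearest-class-centroid "variable node classification" framework supporting
    closed-, open- and mixed-world operation with enrollment of unseen classes,
    class-prediction-based retrieval with an explicit comparison-cost model,
    macro precision/recall evaluation with Monte-Carlo sensitivity analysis and
    PCA post-processing, and a seeded synthetic multi-class image generator so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
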