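Package: phosphenr
Title: End-to-End Optimization of Simulated Phosphene Vision
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint optimization of the full cortical prosthetic-vision
    pipeline: a convolutional stimulation encoder, a differentiable phosphene
    simulator (regular 32x32 electrode grid or arbitrary eccentricity-dependent
    phosphene maps), and a convolutional reconstruction decoder, trained
    end-to-end with a straight-through estimator for binary electrode
    activation. Includes task losses (pixel-wise, deep-feature perceptual,
    class-weighted boundary cross-entropy, stimulation sparsity, spatial
    regularization), synthetic dataset generators (random-character images and
    labeled scenes), image-quality and ROC evaluation metrics, a Canny-based
    conventional-preprocessing baseline, and reproducible experiment presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    png,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
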