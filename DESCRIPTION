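Package: spihits
Title: Single-Hit Diffraction Pattern Classification for Single-Particle Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the single-hit classification stage of X-ray
    single-particle-imaging (SPI) workflows. Provides a synthetic diffraction
    simulator (sphere form factors, multi-particle coherent interference,
    Poisson noise, fluence jitter, two-panel detector masks), a pre-activation
    residual convolutional network trained under heavy class imbalance with
    stratified five-fold cross-validation and on-the-fly augmentation, ensemble
    inference with mirror test-time augmentation, selection-comparison metrics
    (precision/recall/F1, intersection-over-union matrices), and angular-averaged
    power-spectral-density analytics: fringe contrast, sphere-size estimation and
    size filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    pracma,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
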