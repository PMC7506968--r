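Package: fwhteeg
Title: Focal EEG Discrimination via Walsh-Hadamard Entropy Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated discrimination of focal (FC) and non-focal (NFC)
    electroencephalogram records for epileptogenic-zone screening. Signals
    are decomposed by an orthonormal fast Walsh-Hadamard transform, five
    nonlinear entropy features (approximate, sample, permutation, fuzzy and
    log-energy entropy) are computed on the Hadamard coefficients of each
    channel, and a single-hidden-layer neural network trained by
    Levenberg-Marquardt least squares classifies the feature vectors under
    stratified k-fold cross-validation. Includes readers for the two common
    plain-text EEG record dialects, a seeded synthetic two-class generator
    for end-to-end testing, and a one-call experiment pipeline with a
    machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
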