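Package: wptefsvm
Title: Wavelet Packet Tsallis Entropy Features and Fuzzy Support Vector
    Machines for Pathological Brain Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for binary classification of grayscale brain MR slices
    into pathological and healthy classes. Implements a separable
    two-dimensional wavelet packet transform via quadrature-mirror filter
    banks, Tsallis (and Shannon) entropy texture descriptors computed on
    every terminal subband, and a fuzzy support vector machine trained by a
    membership-weighted dual quadratic program solved with a sequential
    minimal optimisation working-set method. Includes stratified repeated
    K-fold cross-validation, grid search over the entropic index q and the
    error penalty C, a synthetic two-class brain phantom generator for
    fully reproducible experiments, and a command-line interface covering
    the offline-training / online-prediction workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    jsonlite
Suggests:
    tiff,
    jpeg,
    kernlab,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
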