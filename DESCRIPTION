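Package: tdpsd
Title: Time-Dependent Power Spectrum Descriptors for Three-Class EEG Classification
Version: 0.1.0
Authors@R:
    person("EEG", "Methods Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification pipeline for resting-state
    EEG aimed at separating Alzheimer's disease (AD), mild cognitive impairment
    (MCI) and healthy controls (HC). Implements the time-dependent power
    spectrum descriptors (TD-PSD): difference-based root-squared spectral
    moments, a lambda power transform, and seven log-domain features including
    sparseness, the irregularity factor and the Teager-Kaiser energy operator.
    Ships a synthetic three-class EEG cohort generator with class-dependent
    band-power profiles and 1/f background, record conditioning (integer-factor
    decimation with a zero-phase Chebyshev anti-alias filter, fixed-window
    cropping), four classifiers (KNN, RBF-kernel SVM trained by SMO, LDA, and a
    small 1-D convolutional neural network trained by backpropagation with
    Adam), and a confusion-matrix / one-vs-rest ROC evaluation layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
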