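Package: ramanpollen
Title: High-Throughput Bright-Field Localization and Raman Chemometrics
    for Pollen Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational pipeline for label-free pollen identification
    from high-throughput screening Raman spectroscopy. Provides
    bright-field particle localization (8-bit conversion, histogram
    thresholding, size filtering, morphological cleanup, blob analysis,
    pixel-to-stage mapping, autofocus Gaussian fitting, tilt-plane
    correction), Raman spectral preprocessing (wavenumber calibration
    against a shift standard, white-lamp intensity calibration, cosmic
    spike removal, extended multiplicative signal correction, area
    normalization, region cropping), and chemometric identification
    (hierarchical clustering with Minkowski distance and cophenetic
    validation for growth-habit screening; per-habit PCA with
    one-vs-one error-correcting-output-codes support vector machines;
    t-SNE visualization with class medians). A seeded synthetic-data
    module generates ground-truthed bright-field images, class-structured
    Raman spectra, and calibration fixtures so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    igraph,
    minpack.lm,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
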