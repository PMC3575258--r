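Package: hdemgmap
Title: High-Density Surface EMG Activation Maps: Quality Control,
    Segmentation and Task Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multichannel surface electromyography recorded with
    2-D electrode arrays (high-density sEMG). Provides a synthetic-data
    generator for grid recordings with known activation structure and
    ground-truth artifacts; per-channel spectral quality features and a
    neighbourhood-threshold expert system for detecting low-quality
    channels, with ROC / precision-recall operating-point tuning and
    inter-rater utilities (majority vote, Fleiss' kappa); RMS activation
    maps with Delaunay-based surface interpolation of rejected channels;
    h-dome segmentation of activation maps via grayscale morphological
    reconstruction and opening; map normalisation to limb-relative
    coordinates, inter-subject averaging and projection statistics; and a
    statistical layer (blocked and repeated-measures Friedman tests,
    Wilcoxon signed rank, leave-one-out linear discriminant classification
    with multiclass performance indexes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    interp,
    jsonlite,
    MASS,
    signal,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
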