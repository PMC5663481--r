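Package: hcfm
Title: High-Content 3D Confocal Fluorescence Image Analysis for
    Environmental Plankton
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An automated analysis pipeline for multi-channel confocal
    Z-stack mosaics of environmental microbial eukaryotes (nano-plankton).
    Detects cell-like objects per field of view with a robust almost-max
    projection and a mean plus 1.5 standard-deviation background threshold,
    removes duplicate detections arising from mosaic tile overlap by
    canonical-field assignment, sub-segments organelles in 3D, computes a
    fixed catalog of 480 morphological, intensity, texture (Haralick, local
    binary pattern, Zernike) and 3D biovolume/overlap descriptors per
    object, and classifies objects into a four-level taxo-morphological
    hierarchy with a seeded 500-tree random forest, including confidence
    scoring, hierarchical cross-validated evaluation, normalized feature
    importance and feature-count reduction. A ground-truthed synthetic
    scene generator emulates the acquisition (five channels, anisotropic
    voxels, 10%-overlap rectangular mosaic) so the whole pipeline is
    testable end to end, and ecological summaries (volume-normalized
    abundances, Spearman covariate correlations) are produced per sample.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    grDevices,
    jsonlite,
    ranger,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
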