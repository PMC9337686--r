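Package: NucleoGAN
Title: Transformer-Based In-Silico Nuclear Labeling from Actin Images
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts fluorescence nucleus images from actin-filament
    images with a convolutional encoder / transformer / decoder
    translator trained under a pixel-weighted L1 reconstruction loss and
    an adversarial loss, then quantifies the actin-nucleus positional
    relationship: nuclei are segmented by thresholding and connected
    components, generated and real nuclei are paired by maximizing
    bounding-box intersection-over-union, centroid distances are
    thresholded at the mean nuclear radius, and the matched fraction is
    compared against geometric random-placement null models with
    binomial tail probabilities and exact or score confidence intervals.
    Ships a synthetic paired-image generator in which the nucleus
    position is a deterministic function of the rendered fiber
    arrangement, so the whole analysis is testable without microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'NucleoGAN-package.R'
    'RcppExports.R'
    'detection.R'
    'io.R'
    'matching.R'
    'metrics.R'
    'nn-core.R'
    'nn-losses.R'
    'nn-model.R'
    'nn-train.R'
    'statistics.R'
    'synthetic-scene.R'
    'synthetic-render.R'
    'pipeline.R'
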