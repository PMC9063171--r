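Package: grainmetry
Title: Image-Based Wheat Grain Morphometry and Mean Grain Weight Prediction
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating wheat mean grain weight (MGW) from top-view
    images of non-touching grains on a bright background. Provides bicubic
    resolution enhancement, HSB brightness thresholding and connected-component
    extraction of grains, per-grain shape descriptors in the particle-analysis
    convention (area-preserving moment-based ellipse fit, rotating-calipers
    Feret diameters, chain-code perimeter, circularity, solidity), a catalogue
    of empirical weight-predictive indices built from those descriptors, linear
    MGW models with k-fold cross-validation plus published reference
    coefficients, and a synthetic grain-scene generator with ground truth for
    end-to-end validation without a physical imaging system.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    grDevices,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
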