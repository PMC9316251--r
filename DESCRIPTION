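Package: torsoshape
Title: Torso Shape Analysis for Predicting Body Fat Magnitude and Distribution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for extracting geometric-morphometric shape descriptors from
    3D torso point clouds and relating them to body composition. Implements
    torso segmentation and alignment, cross-section band extraction with
    centroid-size scaling, periodic smoothing-spline contour fitting, complex
    Fourier shape descriptors (250 coefficients per torso), a 10-component PCA
    shape space, anthropometric and volume/surface-area extraction with
    allometric height normalization, emulation of air-displacement
    plethysmography and segmental bioimpedance reference measurements, and a
    model-comparison engine (exhaustive 5-of-10 shape-subset search, stepwise
    AIC regression with pairwise interactions, 10-fold cross-validation and
    Johnson relative weights) for predicting body-fat percentage and the
    trunk:peripheral fat ratio. A synthetic-cohort generator provides fully
    specified torso surfaces and ground truth so the entire pipeline is
    testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
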