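Package: stereobird
Title: Stereo-Vision Bird Detection, Localization and Collision Avoidance for Wind Turbines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and simulating a camera-based bird
    collision-avoidance system for wind turbines. Implements the optical
    design calculator (field of view, on-image bird size, sensor/lens
    feasibility), a tilted vertical-baseline stereo model with closed-form
    pixel-quantization uncertainty bounds, a two-frame motion-detection
    pipeline (Gaussian smoothing, frame differencing, contour measurement
    via the shoelace formula, region-of-interest cropping), a compact
    convolutional neural network for bird/non-bird identification, physical
    size estimation with three-class bird size classification, and a
    configurable deterrent/turbine-stop decision policy. A synthetic scene
    generator renders stereo frame pairs of triangle bird silhouettes at
    known 3D positions, providing exact ground truth for end-to-end
    validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
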