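Package: flagbeat
Title: Flagellar Beat Analysis for Tethered Sperm in Dark-Field Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the flagellar beat of single tethered sperm from
    high-speed dark-field movie stacks. Provides frame preprocessing
    (Gaussian blur, rolling-ball background subtraction), sub-pixel midline
    tracing (triangle thresholding, skeletonization, Gaussian ridge
    refinement along local normals), curvature-angle kinematics on a fixed
    arc-length grid, per-position beat-frequency estimation by Fourier
    analysis with the (f1+f2)/2 merge, the local beat-asymmetry statistic
    (absolute time-averaged curvature angle), condition comparisons with
    pointwise two-way ANOVA and Tukey-adjusted contrasts, one-beat-cycle
    waveform projections, and a synthetic traveling-wave flagellum
    simulator so that every stage is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    yaml,
    jsonlite,
    emmeans
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
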