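Package: hyphoshell
Title: Cell-Wall Thickness Mapping and Mechanical-Feedback Modeling of Fungal Tip Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how filamentous fungi build and deform their cell
    wall during tip growth. Provides a synthetic two-channel microscopy phantom
    generator with known wall geometry; subresolution wall-thickness mapping by
    Gaussian peak fitting of paired membrane/lectin intensity profiles sampled
    normal to the cell contour, with chromatic-shift correction and
    inside/outside background-asymmetry compensation; thin-shell estimates of
    wall Young's modulus, surface modulus, and turgor pressure from deflation
    and osmotic-shock measurements; an ordinary-differential-equation model of
    tip growth coupling exocytic-vesicle accumulation, wall thickness, and wall
    strain rate through a mechanical feedback, with steady-state, stability,
    calibration, and perturbation-scenario analyses; and time-series utilities
    (normalized cross-correlation, relative fluctuation, bleach correction,
    fiducial-mark drift).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
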