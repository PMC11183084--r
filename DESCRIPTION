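Package: strutkit
Title: Optical Printability Assessment for Extrusion Bioprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative evaluation of extrusion-bioprinting printability
    from optical observations of the deposited and the hanging strut.
    Models the deposited strut as a parabolic cap and recovers its width,
    height, vertex curvature and cross-section from the apparent rotation
    of a diagonally striped background seen through the strut acting as a
    cylindrical lens. Fits complete-wetting (unbounded 1/7-power) and
    partial-wetting (saturating) spreading laws to time-resolved strut
    widths, and estimates elongational viscosity versus strain rate from
    the trajectory and diameter profile of the strut hanging from the
    nozzle via a force balance on cylindrical elements. Includes image
    extraction (scale calibration, edge contours, centerline and diameter,
    stripe-angle measurement) and fully ground-truthed synthetic data and
    image generators so every estimator is testable without laboratory
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    signal,
    pracma,
    deSolve,
    png,
    jsonlite,
    EBImage,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
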