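Package: nervestim
Title: Simulation of Extracellular Stimulation and Block of Peripheral Nerve Fibers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for modeling electrical stimulation of
    peripheral nerves with cuff electrodes: representation and generation of
    2D nerve cross-sectional morphology (segmented-mask ingestion or mock
    elliptical fascicle generation), parameterized cuff contact placement,
    volume-conductor basis potentials from an analytic anisotropic
    point-source solver or a finite-difference solver for inhomogeneous
    tissue (endoneurium, perineurium thin layers, epineurium, surrounding
    medium), fiber coordinate sets with MRG-interpolated myelinated and
    HH-type unmyelinated discretizations, stimulation waveform generation,
    implicit cable-model simulation of fiber responses, bisection searches
    for activation and kilohertz-frequency block thresholds, and analysis
    products such as threshold heatmaps and recruitment curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    mgcv,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    png,
    EBImage,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
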