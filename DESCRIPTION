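Package: bubblespec
Title: Single-Microbubble Spectroscopy and Coating Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Characterization of single phospholipid-coated microbubbles
    (ultrasound contrast agents) from ultra-high-speed radius-time
    recordings and two-channel 3D confocal stacks. Fits the linearized
    coated-bubble oscillator model to per-frequency oscillation
    amplitudes to estimate shell elasticity, shell viscosity, and
    resonance frequency; classifies subharmonic and second-harmonic
    responses from radius-time spectra; quantifies acoustic stability
    (deflation) and population variability; and quantifies ligand
    inhomogeneity, liquid-condensed phase area, and buckles on the
    coating with a 32-part equal-area spherical partition. Includes
    seeded synthetic-data generators (oscillator sessions, voxelized
    coated shells, size distributions) with recorded ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
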