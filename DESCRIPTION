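Package: scnphase
Title: Circadian Phase Estimation and Virtual Slicing Dynamics for the
    Suprachiasmatic Nucleus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the oscillatory organisation of the
    suprachiasmatic nucleus (SCN). Extracts per-pixel circadian amplitude and
    phase from hourly PER2::LUC bioluminescence movies by Fourier analysis,
    fits the linear model relating differences in single-frame brightness to
    differences in phase, calibrates a single-time-point ("snapshot") phase
    model by tuning the Kuramoto order parameter of the estimated phases, and
    applies the calibrated model to tables of 3D neuron positions and PER2
    intensities from cleared whole-mount tissue. Includes nearest-neighbour
    direction anisotropy summaries, Kuramoto coupled-oscillator simulation on
    distance-plus-random connectivity graphs, virtual sectioning of the neuron
    cloud in coronal, sagittal and horizontal orientations, and deviation
    statistics quantifying the dynamical damage done by each slicing
    orientation. Synthetic generators for both data modalities carry ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    sandwich,
    stats,
    tools,
    methods,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
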