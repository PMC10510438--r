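Package: anepps
Title: Voltage-Dependent Fluorescence Analysis for Membrane-Bound di-8-ANEPPS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the voltage-dependent fluorescence of the
    potentiometric styryl dye di-8-ANEPPS embedded in a lipid membrane.
    Converts ground- and excited-state energy-gap ensembles into peak
    absorption and emission wavelengths with empirical vibrational offsets,
    computes Stokes shifts, voltage-response fits and block-average
    uncertainties; models the emission line as a Lorentzian with a
    voltage-dependent peak to calibrate dual-wavelength (620/560 nm)
    emission ratiometry against peak shifts; derives the dimensionless
    transmembrane potential fraction profile f(z) from paired electrostatic
    potential maps; and summarises probe configuration (depth, tilt,
    density profiles, range of motion). A synthetic-trajectory module
    generates stationary autocorrelated surrogate data with prescribed
    statistics so the full pipeline runs without molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
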