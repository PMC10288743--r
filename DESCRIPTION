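Package: fnirsdoc
Title: Simulation and Analysis of fNIRS Hemodynamic Responses in Disorders of
    Consciousness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing residual consciousness from prefrontal
    functional near-infrared spectroscopy (fNIRS) recordings under a
    block-design auditory paradigm (subject's own name versus motor imagery).
    Provides a seeded generator of dual-wavelength optical recordings with
    group-specific hemodynamic response profiles and physiological noise, the
    standard preprocessing chain (modified Beer-Lambert law inversion,
    zero-phase Butterworth band-pass, correlation-based signal improvement,
    trial rejection, z-scoring), stimulus-locked epoching with block averaging
    and mean-concentration / fitting-slope features, and the rank-based group
    statistics (tie-corrected Mann-Whitney U and Kruskal-Wallis) used to
    compare healthy controls with minimally conscious and vegetative state
    patients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
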