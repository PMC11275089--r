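Package: capaxon
Title: Capacitive Neuromodulation of a Multi-Compartment Hodgkin-Huxley Axon
    and Two-Arm Trial Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the effect of a skin-applied capacitive (dielectric)
    element on action-potential trains in a segmented Hodgkin-Huxley axon,
    and analyses two-arm pre/post observational gait-and-balance studies.
    Provides the single-compartment Hodgkin-Huxley core (gating kinetics,
    ionic currents, membrane equation with an added user capacitance), a
    multi-compartment axon with stimulus injection and a dielectric element
    modelled as a parallel capacitor and/or an opposing impressed current
    generator, spike-train detection and modulation metrics, a synthetic
    two-arm Parkinson's-disease cohort generator calibrated to reproduce
    published test statistics in expectation, and the matching statistical
    battery (Shapiro-Wilk screening, paired t tests, Mann-Whitney U,
    chi-square) with report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
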