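Package: fusiform
Title: Tinnitus Classification from Gap-Startle Behavior and Fusiform-Cell Biophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for noise-induced tinnitus studies in mice.
    Implements the gap-prepulse-inhibition behavioral pipeline (startle-trial
    quality control, gap-startle and PPI ratio averaging, Gaussian-null
    thresholding of post-minus-pre ratio changes, tinnitus/non-tinnitus
    classification and incidence comparison), a seeded synthetic-cohort
    generator for end-to-end testing, a single-compartment conductance-based
    fusiform-cell simulator with Boltzmann-gated KCNQ and HCN currents and
    pharmacology switches, extraction of the standard biophysical features
    (XE991-sensitive tail currents, conductance-voltage Boltzmann fits, HCN
    sag ratio, input resistance, resting potential, spike parameters, firing
    rate), and the accompanying statistical decision tree (Monte-Carlo
    Lilliefors normality gate, parametric and nonparametric branches, exact
    incidence tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
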