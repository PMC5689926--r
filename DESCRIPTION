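Package: overlaptriage
Title: A-Priori Prediction of Dosimetric Eligibility for Hypofractionated
    Prostate Radiotherapy from PTV-OAR Overlap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision support for triaging prostate radiotherapy patients
    before treatment planning. Computes the fractional overlap of the bladder
    wall and rectal wall with the planning target volume (PTV) from 3D
    structure masks or planar contour stacks, combines the two fractions in
    quadrature into a single overlap metric, learns a single-threshold
    eligibility classifier from a labelled cohort, evaluates it by repeated
    stratified two-fold cross-validation, derives radial
    feasible/uncertain/not-feasible decision zones, renders the
    decision-support plot, and checks cumulative dose-volume histograms
    against the hypofractionation trial dose constraints. Includes
    seed-reproducible synthetic cohort, anatomy and DVH generators so the
    full pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
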