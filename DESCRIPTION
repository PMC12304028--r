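Package: pegaspk
Title: Population and Non-Compartmental Pharmacokinetics of Pegaspargase
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the pharmacokinetic and endpoint analysis of
    pegaspargase (pegylated E. coli L-asparaginase) trials in acute
    lymphoblastic leukemia. Implements a one-compartment structural model
    with parallel linear and Michaelis-Menten (saturable) elimination and
    IV-infusion or first-order intramuscular input; covariate-to-parameter
    mapping (body surface area power models, categorical fractional
    shifts); a protocol-faithful synthetic cohort generator with
    BSA-thresholded dosing, induction/re-induction sampling schedules,
    log-normal between-subject variability and LLOQ censoring;
    non-compartmental analysis (Cmax, AUC by linear-up/log-down trapezoid,
    terminal slope, half-life, clearance, Vss); nonlinear mixed-effects
    estimation by first-order conditional estimation with interaction
    (FOCEI) including stepwise covariate model building and visual
    predictive checks; covariate forest-plot exposure simulation from the
    variance-covariance matrix of estimates; and trial endpoint statistics
    (exact Clopper-Pearson intervals for asparaginase-activity threshold
    attainment, Kaplan-Meier survival, response rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    MASS,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
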