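Package: efvpopk
Title: Population Pharmacokinetics of Efavirenz with Pharmacogenetic Dose
    Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear mixed-effects modelling of steady-state efavirenz
    plasma concentrations with a one-compartment oral-absorption model.
    Implements a first-order conditional estimation objective with
    interaction (FOCE-I), empirical-Bayes random-effect estimation,
    stepwise covariate selection on the change in objective function
    value, and Monte-Carlo simulation of therapeutic-window attainment
    to derive CYP2B6 genotype-, weight- and sex-stratified daily dose
    recommendations against the 1-4 ug/ml therapeutic window. Includes a
    synthetic cohort generator emulating the demographic and
    pharmacogenetic structure of an HIV/TB treatment cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    withr,
    jsonlite
Config/testthat/edition: 3
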