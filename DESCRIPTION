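Package: migkin
Title: Kinetics of Acetyl Group Migration and Hydrolysis in
    Oligosaccharide Model Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modeling intramolecular acetyl group migration and
    hydrolysis in partially acetylated oligosaccharides as first-order
    reaction networks.  Provides built-in reaction schemes for xylan and
    glucan model trisaccharides, stiff ODE simulation of species mole
    fractions with hydroxide-concentration (pH) scaling of the rate
    constants, nonlinear least-squares estimation of rate constants from
    NMR-derived concentration time series (simplex followed by
    Levenberg-Marquardt), a thermochemical layer linking rate constants,
    Eyring activation barriers, hydroxyl pKa values and pH-dependent
    observed rates of the anionic migration mechanism, and a synthetic-data
    generator for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
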