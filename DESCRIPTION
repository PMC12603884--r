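Package: sedpkpd
Title: Population Pharmacokinetic-Pharmacodynamic Modelling of Clonidine
    and Midazolam Sedation in Ventilated Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structural pharmacokinetic models for clonidine and for
    midazolam with its 1-OH metabolite (allometric weight scaling and
    postmenstrual-age maturation of clearance), an inhibitory sigmoid Emax
    model of the COMFORT-B sedation score with a postanesthesia washout
    effect and a K-PD co-medication effect, and a Laplace-approximation
    nonlinear mixed-effects estimator with bootstrap, prediction-corrected
    visual predictive checks and likelihood-ratio covariate testing.
    Includes a two-step pharmacogenetic screen of SNPs against individual
    clearances, a virtual-trial generator emulating a blinded randomized
    sedation trial in a pediatric intensive care unit, and forward
    dose-regimen simulation for virtual populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, graphics, grDevices, utils
Suggests: testthat (>= 3.0.0), deSolve, lme4, jsonlite, withr
Config/testthat/edition: 3
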