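Package: glucoloop
Title: Closed-Loop Glucose Control Simulation for Critical Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: In-silico evaluation of fully automated closed-loop glucose
    control in critically ill adults. Provides a virtual-patient model of
    glucose-insulin compartment kinetics with a seeded cohort generator, a
    synthetic continuous glucose monitor with blood-to-interstitial lag,
    calibration error and dropouts, an adaptive model-predictive controller
    dosing insulin and 20% dextrose every five minutes under safety clamps,
    an hourly intravenous sliding-scale comparator protocol, a randomized
    in-silico trial engine using covariate minimization, and the endpoint
    battery (time in range, glycemic episodes, sensor accuracy, exact
    Mann-Whitney U and unpaired t tests) used to summarize such trials.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
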