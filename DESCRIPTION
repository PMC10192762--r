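Package: bifrail
Title: Bistable Toggle-Switch Modelling of Frailty Biomarkers and Mobility Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic modelling of frailty trajectories in older adults from a
    pair of mutually inhibitory serum biomarkers, insulin-like growth factor 1
    (IGF-1) and interleukin-6 (IL-6). The biomarkers follow a Hill-type
    double-negative feedback (toggle switch) system coupled to compartmental
    prevalence scores for mobility, mobility disability and death with a
    Gompertz-type time-dependent hazard. Provides the model fitting routine
    against literature-derived trend, survival and disability constraints,
    steady-state enumeration with stability classification, basin-of-attraction
    scans, separatrix and switch-curve analysis, cohort outcome envelopes,
    phenotype classification, and generators for the synthetic populations and
    calibration fixtures the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
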