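Package: xenotrial
Title: Preclinical Xenograft Efficacy Evaluation and Tumor-Growth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for murine xenograft efficacy studies evaluated
    with Pediatric Preclinical Testing Consortium style response criteria:
    time-to-tumor-quadrupling events with log-linear interpolation,
    Kaplan-Meier median event-free survival with censored-median bounds and
    EFS T-C / T/C contrasts, the Peto-Peto modified Gehan-Wilcoxon test
    (asymptotic and exact permutation), per-mouse objective response
    classification (PD1/PD2/SD/PR/CR/MCR) with group median scoring and
    panel-level response rates, tumor growth inhibition and body-weight
    metrics, and a stochastic piecewise-exponential tumor-growth simulator
    with dosing schedules and toxicity-driven dosing holidays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
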