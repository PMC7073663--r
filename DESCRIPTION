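Package: pairct
Title: Personalized Advantage Index Analysis for Two-Arm Trials via Bayesian Model Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates two-arm randomized trials with known per-patient
    treatment-advantage ground truth, screens and imputes mixed-type baseline
    covariates with an iterative random-forest procedure, fits per-arm
    Bayesian model averaging for Gaussian linear outcome models under the
    Zellner-Siow null-based prior (exact enumeration or a hybrid MCMC plus
    sampling-without-replacement scheme), and derives leave-one-out factual
    and counterfactual outcome predictions yielding the Personalized
    Advantage Index (PAI) and its cohort summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
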