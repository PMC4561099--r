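Package: cidnet
Title: Supervised Transcription-Factor Network Analysis and Prognostic
    Signature Discovery from Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds supervised transcription-factor regulatory networks from
    probe-level expression cohorts by combining an empirical-distribution-based
    nonlinear association statistic (the coefficient of intrinsic dependence,
    CID) with the Pearson correlation (GPCC) under a union calling rule, with
    permutation-calibrated significance.  Couples the called networks with
    clinical covariate screens (one-way ANOVA pools), percentile-stratified
    Kaplan-Meier/log-rank prognostic typing across estrogen-receptor-defined
    cohorts, and Cox proportional-hazards evaluation to extract consensus
    poor-prognosis and antagonistic favorable gene signatures.  Includes a
    synthetic cohort generator with planted regulatory edges and survival
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
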