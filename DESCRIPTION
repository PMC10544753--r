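Package: nashscreen
Title: Non-Invasive NASH Screening Scores with Survey-Weighted Prevalence
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying probable non-alcoholic steatohepatitis (NASH)
    in population surveys without liver biopsy. Implements three validated
    clinical scoring systems (the HAIR score, the Gholam score, and the NASH
    liver fat score) together with their combined all-three-positive and
    at-least-one-positive classifications, cohort eligibility and exclusion
    rules for ultrasound-based fatty-liver studies, serial and parallel
    composition of screening sensitivity and specificity, and design-based
    estimation for complex surveys: Taylor-linearized weighted prevalence,
    direct age standardization, Rao-Scott adjusted chi-squared tests, and
    weighted multinomial logistic regression with linearized sandwich
    covariance. A synthetic-cohort generator with a three-level latent liver
    state and a stratified multi-PSU design supports end-to-end testing and
    simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
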