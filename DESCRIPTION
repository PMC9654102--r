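Package: hfssm
Title: Scoring and Brief-Screener Evaluation for the Household Food
    Security Survey Module
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores the 10-, 6- and 2-item adult Household Food Security
    Survey Module (HFSSM) and the Australian single-item food-security
    measure, classifies households into food-security severity levels,
    and evaluates brief two-item OR-rule screeners against the 10-item
    reference standard (three or more affirmed conditions) by
    sensitivity, specificity and accuracy, overall and within
    sociodemographic subgroups.  Includes a seeded latent-severity
    (two-parameter logistic) respondent simulator with a quadrature
    oracle for population-level screener operating characteristics, so
    the whole pipeline can be exercised and validated without access to
    confidential survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
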