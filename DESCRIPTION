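Package: awrat
Title: Animal Welfare Risk Assessment Tool Scoring, Completeness and
    Reliability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes weighted composite risk ratings for livestock welfare
    assessments made with the Animal Welfare Risk Assessment Tool (AWRAT),
    together with a Measure of Completeness (MOC) that weights missing
    factor ratings by topic importance. Includes the validation pipeline
    used to relate the risk rating to an overall welfare rating (record
    cleaning, MOC-stratified linear regression with adjusted R-squared),
    ANOVA-based intraclass correlation coefficients for intra- and
    inter-observer reliability of visual-analogue ratings, a synthetic
    cohort generator with known latent structure, and a command-line
    interface over CSV inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
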