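Package: afwatch
Title: Weakly Supervised Surveillance of Wearable-Device Atrial
    Fibrillation Prediagnoses in Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electronic-health-record based postmarket
    surveillance of consumer wearables that alert users to possible
    atrial fibrillation (AF).  Implements rule-based labeling functions
    over clinical notes mentioning wearable devices, a generative label
    model fit by expectation-maximization that combines labeling-function
    votes into probabilistic labels, a noise-aware n-gram text classifier
    trained on those labels, and a retrospective cohort analysis of the
    classifier output (index-note selection, prior-AF washout, 60-day
    diagnosis windows, CHA2DS2-VASc scoring, Welch and chi-squared group
    comparisons, relative risk).  A seeded synthetic-EHR generator
    produces notes with known ground truth plus linked structured tables
    so the whole pipeline runs end to end without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
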