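Package: gabsence
Title: Parametric G-Formula for Sickness Absence Under Hypothetical
    Improvements in Psychosocial Work Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hypothetical improvements in psychosocial work factors
    and estimates the resulting changes in total, short-, intermediate- and
    long-term sickness absence rates with the parametric g-formula. Provides
    COPSOQ-style 0-100 scale scoring and quartile categorization of Likert
    items, classification of absence spells into duration terms, inverse
    probability weighting for employees with incomplete exposure data,
    ridge-penalized Poisson outcome models with fixed-working-hours offsets,
    etiologic (most vs. least desirable) and realistic (most desirable vs.
    observed) counterfactual rate ratios, and Bag of Little Bootstraps
    confidence intervals. Includes a synthetic cohort generator with recorded
    ground truth for parameter-recovery testing, and an end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
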