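Package: amdrisk
Title: Risk Classification Models for Age-Related Macular Degeneration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds and evaluates risk-classification models for age-related
    macular degeneration (AMD) from six established susceptibility factors:
    age at examination, cigarette smoking, and additive genotype encodings of
    CFH Y402H, ARMS2 A69S, CFB R32Q, and C3 R102G. Three classifiers are
    provided - an additive logistic regression model with threshold and
    ROC-based optimal-threshold classification, a multifactor dimensionality
    reduction (MDR) cell-ratio classifier with explicit "could not classify"
    handling, and grammatical evolution of neural networks (GENN) with a
    balanced-accuracy fitness function - together with a two-of-three
    consensus rule. Evaluation covers sensitivity, specificity, PPV, NPV and
    overall correct classification under dual denominators, plus
    prevalence-adjusted predictive values for translating case-control
    estimates to population screening settings. A synthetic case-control
    cohort generator with Hardy-Weinberg genotype sampling and a logistic
    generative model supports fully reproducible end-to-end pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
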