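Package: sleepmarkr
Title: Blood Transcriptome Biomarker Panels for Acute and Chronic Sleep Debt
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and validation of multivariate blood mRNA biomarker
    panels for sleep debt status. Implements elastic-net and ridge penalized
    regression by cyclic coordinate descent (linear and logistic families),
    lambda tuning by repeated stratified 10-fold cross-validation with the
    mean-of-selected-lambdas rule, subject-aware data partitioning (subject-
    disjoint and condition-crossed training/validation splits), leave-one-
    subject-out cross-validation, a-priori feature screening (time-awake
    trend, cosinor circadian modulation, paired sleep-condition contrast),
    and classification/regression performance metrics (accuracy, sensitivity,
    specificity, Matthews correlation coefficient, R-squared, Cohen's d).
    Includes a synthetic crossover sleep-deprivation cohort generator with
    per-feature ground truth for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
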