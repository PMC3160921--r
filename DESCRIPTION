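Package: vametrics
Title: Robust Validation Metrics for Verbal Autopsy Cause Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metrics and study-design tools for validating verbal autopsy (VA)
    cause-of-death assignment methods. Implements chance-corrected concordance
    (CCC) for individual cause assignment, partial chance-corrected concordance
    PCCC(k) for ranked or probabilistic predictions, and CSMF accuracy for
    cause-specific mortality fraction estimation, together with the
    Dirichlet-resampling protocol that varies the cause composition of test
    datasets and reports stabilized medians across draws. Includes a
    misclassification-matrix simulator that demonstrates why legacy metrics
    (sensitivity, specificity, Cohen's kappa, CSMF errors) are unstable across
    test-set cause compositions, and reporting helpers that emit full confusion
    matrices alongside every summary metric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
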