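Package: tempentropy
Title: Entropy Features and Logistic Classification of Body Temperature
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes amplitude-based (approximate entropy, sample entropy)
    and ordinality-based (permutation entropy) regularity statistics for
    physiological time series, screens them for redundancy by correlation,
    and fits univariate and bivariate logistic classifiers with full
    diagnostics (Wald tests, odds ratios, deviance, Cox-Snell and Nagelkerke
    pseudo-R2, AIC, ROC/AUC) and paired leave-one-out validation. Ships a
    reference feature table from a 30-subject body-temperature monitoring
    cohort (16 healthy, 14 febrile) and a seeded generator of surrogate
    two-class temperature cohorts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
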