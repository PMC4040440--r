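Package: polyrisk
Title: Naive Bayes Posterior Probabilities of Disease and Prognostic
    Utility of Polygenic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genetic-based disease prediction under multilocus
    Naive Bayes models: posterior probabilities of disease (PPD) for
    genotype profiles, exact population distributions of the PPD under
    parameterised genetic architectures, threshold-based actionability
    analysis (C1/C2 fractions), genetic risk scores with quantile risk
    stratification and case-control intercept calibration, prognostic
    utility metrics (ROC/AUC, PPV/NPV, net reclassification improvement,
    Kullback-Leibler divergence), a categorical Naive Bayes genotype
    classifier with stratified cross-validation, and a seeded cohort
    simulator generating data with the exact statistical structure the
    models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
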