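Package: synophen
Title: Synovial Molecular Phenotyping and Serum Biomarker Subgroup Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised discovery of synovial molecular phenotypes
    (lymphoid, myeloid, low-inflammatory, fibroid) from bulk expression
    cohorts, derivation and quartile-trimmed-mean scoring of
    phenotype-specific gene signatures with empirical-Bayes moderated
    t-statistics, mapping of signatures onto external cohorts with ROC/AUC
    evaluation against clinical response, and serum-biomarker subgroup
    analysis of two-arm trials: median splits with left-censored values,
    subgroup odds ratios with Wald or profile-likelihood intervals, Fisher
    exact tests, and one- and two-dimensional subpopulation treatment
    effect pattern plots (STEPP). Includes synthetic-cohort generators that
    emulate the statistical structure of a 49-sample expression cohort with
    five planted phenotype groups and a 198-patient two-arm trial with two
    correlated log-normal biomarkers, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    limma
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    jsonlite
Config/testthat/edition: 3
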