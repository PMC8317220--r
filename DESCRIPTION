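Package: obesotype
Title: Metabolic Subtyping of Obesity from OGTT-Derived Clinical Variables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised metabolic phenotyping of obesity cohorts from three
    routine clinical variables: the oral glucose tolerance test (OGTT) glucose
    and insulin areas under the curve and serum uric acid. Implements
    sex-stratified k-means and two-step (log-likelihood distance, Schwarz BIC)
    clustering with silhouette-based selection of the cluster count, a
    deterministic labeling of the four metabolic subtypes (MHO, HMO-U, HMO-I,
    LMO), nearest-center assignment of external cohorts to a fitted model with
    accuracy/sensitivity/specificity and Jaccard stability reporting, stepwise
    linear-regression imputation of AUCs from partial OGTT sampling,
    comorbidity statistics (sex- and age-adjusted odds ratios, chi-square,
    ANOVA/ANCOVA with Bonferroni post hoc), insulin sensitivity and secretion
    indices (HOMA, IGI, Matsuda WBISI, disposition indices), and a calibrated
    synthetic-cohort generator so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
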