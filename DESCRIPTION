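Package: pdacStack
Title: Diagnosis-Specific Stacked Ensembles for Pancreatic Cancer Serum Biomarker Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for developing and evaluating serum-protein classifiers that
    separate pancreatic ductal adenocarcinoma (PDAC) from the benign and healthy
    conditions that confound it in symptomatic secondary-care cohorts. The
    package couples a synthetic cohort generator (Olink-style NPX marker panels,
    clinical covariates, symptoms, batch structure with bridge samples) with a
    complete modelling protocol: Firth bias-reduced logistic regression with
    profile penalized-likelihood intervals, stratified discovery/validation
    splitting, reference-sample bridging normalization, univariate screens,
    class-imbalance subsampling inside cross-validation folds, recursive feature
    elimination under leave-one-out cross-validation, diagnosis-specific base
    learners stacked by a logistic meta-model, tree-based comparators,
    permutation feature importance, and ROC evaluation at fixed specificity with
    stratified-bootstrap inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    S4Vectors,
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Classification, Proteomics, BiomedicalInformatics, StatisticalMethod
RoxygenNote: 7.3.3
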