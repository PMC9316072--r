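Package: ecshock
Title: Detecting Stroke-Volume Decrease from Electrical Cardiometry under
    Simulated Central Hypovolaemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for detecting a clinically
    relevant (>= 20 percent) stroke-volume decrease -- compensated shock --
    from non-invasive electrical cardiometry (thoracic bioimpedance)
    measurements during graded lower-body negative pressure (LBNP).
    Provides a synthetic cohort generator emulating the 5-stage LBNP
    protocol with subject-level heterogeneity and beat-to-beat noise;
    window-based descriptive-statistic feature engineering with z-score
    standardisation; within-subject relational observations labelled by
    echocardiographic stroke-volume decline; grey-zone ROC diagnostics
    (bootstrap AUC confidence intervals and Youden-optimal cutoff
    distributions); stage-wise nonparametric statistics and correlation
    analysis; and subject-grouped leave-two-out nested cross-validation of
    KNN, naive Bayes, random forest and SVM classifiers with entropy-filter
    and wrapper feature selection and hyperparameter grid search.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
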