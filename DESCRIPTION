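Package: ddihybrid
Title: Hybrid Chemical and CYP450 Interaction Features for Multiclass
    Drug-Drug Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the type of a directional drug-drug interaction
    (victim affected by perpetrator) from structure alone.  Ordered drug
    pairs are featurized two ways: molecular descriptor vectors computed
    from SMILES are combined with pairwise operators (full cross product,
    concatenation, or sum-and-product), and each drug's cytochrome P450
    metabolism profile is encoded into signed victim/perpetrator vectors
    whose elementwise product captures inhibition and induction of the
    victim's metabolising enzymes.  A consensus of random-forest and
    univariate ANOVA-F rankings selects the informative chemical features,
    SMOTE rebalances the long-tailed class distribution, and five
    classifier families (naive Bayes, decision tree, random forest,
    multinomial logistic regression, gradient boosting) are tuned by
    stratified cross-validated grid search.  Includes per-class
    precision/recall/F1 and one-vs-rest ROC/AUC reporting, a synthetic
    drug-library and interaction generator with a planted, documented
    decision rule for end-to-end validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang (>= 1.0.0),
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
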