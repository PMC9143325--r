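Package: ditpqsar
Title: QSAR Classification Pipeline for Drug-Induced Immune Thrombocytopenia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A binary QSAR (quantitative structure-activity relationship)
    pipeline for predicting drug-induced immune thrombocytopenia (DITP)
    toxicity from molecular structure. Reads labeled SMILES tables, computes
    fingerprint and descriptor feature blocks (MACCS, an 881-bit
    substructure-key fingerprint in the public PubChem layout, hashed
    path fingerprints, open-provider molecular descriptors), streamlines and
    min-max normalizes features, rebalances training folds with SMOTE,
    selects among seven classifier families by repeated stratified
    cross-validation, quantifies prediction reliability with a
    Euclidean-distance applicability domain, and mines structural alerts by
    information gain and class-enrichment frequency. A seeded synthetic-data
    generator emulates the statistical structure of fragment/descriptor
    datasets so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils,
    class,
    e1071,
    randomForest,
    nnet,
    rpart,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
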