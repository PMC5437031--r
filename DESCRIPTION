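Package: CarcinoEnsemble
Title: Ensemble Fingerprint Models for Chemical Carcinogenicity Prediction
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts rat carcinogenicity of organic chemicals from SMILES
    structures. Twelve molecular fingerprint families (hashed path
    fingerprints, MACCS/PubChem/Klekota-Roth style structural keys and their
    count variants, E-state atom types, 2D atom pairs) feed fingerprint-specific
    base classifiers (radial SVM, random forest, gradient-boosted trees) that
    are fused into ensemble models by probability averaging. Includes compound
    curation (salt stripping, element and mixture filters), zero-variance and
    pairwise-correlation feature selection, repeated stratified five-fold
    cross-validation with accuracy/sensitivity/specificity/AUC reporting,
    learning-curve experiments, Gini-importance substructure mining, consensus
    batch screening of compound libraries, and a seeded synthetic-fixture
    generator with planted substructure-label associations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    igraph,
    ranger,
    e1071,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    pROC,
    randomForest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
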