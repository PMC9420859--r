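Package: moonsvm
Title: Moonlighting Protein Classification from Sequence Features with LDA and Bagging-SVM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting moonlighting proteins (proteins with two or
    more autonomous functions) from primary sequence. Implements three
    sequence-derived feature encoders (pseudo-amino-acid composition,
    SVMProt-188D composition/transition/distribution descriptors, and
    pseudo-PSSM evolutionary features), a closed-form two-class Fisher linear
    discriminant projection, a bagging ensemble of linear support vector
    machines, and a stratified k-fold cross-validation harness with
    confusion-matrix metrics and exact rank-based AUC. A seeded synthetic
    sequence and PSSM generator makes the whole pipeline testable without any
    external database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    class,
    rpart,
    nnet,
    randomForest,
    xgboost,
    MASS,
    pROC,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
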