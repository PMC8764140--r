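Package: kcrcontact
Title: Contact-Aware Feature Encoding for Lysine Crotonylation Site
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature encoders, feature selection, class balancing,
    classifiers and evaluation metrics for predicting lysine
    crotonylation (Kcr) sites in proteins.  Alongside classical
    sequence-window encoders (AAC, AAPC, binary, CKSAAP, EAAC, EGAAC,
    PSSM windows) it implements contact-aware encoders that exploit
    predicted residue-residue contact maps: residue-residue composition
    (RRC) and residue-residue pair composition (RRPC).  Includes
    chi-square and information-gain feature selection, random
    undersampling for imbalanced data, grid-searched SVM / random
    forest / logistic-regression classifiers with stratified
    cross-validation, a full metric panel (Sn, Sp, Acc, MCC, Recall,
    Precision, F1, ROC/AUC), and a synthetic-data generator with
    plantable sequence and contact signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    ranger,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
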