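Package: pathrepo
Title: Drug Repositioning from Heterogeneous Networks via Meta-Path
    Commuting Matrices and SVD Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-disease treatment associations from three
    interaction layers (drug-protein, disease-protein, drug-disease)
    without any similarity data. Five meta paths over the heterogeneous
    drug-protein-disease network are summarised as commuting matrices
    whose entries count path instances; each matrix is factorised by
    truncated singular value decomposition to obtain low-dimensional
    latent features of drugs and diseases; reliable negative pairs are
    filtered from the unlabeled set by requiring that drug and disease
    share no interacting protein; and one random-forest base classifier
    per meta path is combined by score averaging into an ensemble
    predictor. Includes a seeded synthetic-network generator with
    planted shared-protein signal, 5-fold cross-validation with
    test-edge masking, precision-recall and ROC evaluation, candidate
    ranking, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    ranger,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
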