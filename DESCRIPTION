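Package: batchalign
Title: Joint Batch-Effect Calibration and Classification for Omics Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes batch effect between a labeled source batch and an
    unlabeled target batch of metabolomics or mass-cytometry feature tables by
    jointly training three small neural networks: a shared calibrator that maps
    both batches into a common latent space where their maximum mean
    discrepancy (MMD) is minimized, per-batch reconstructors that force the
    latent code to retain the sample information, and a discriminator that
    learns the class labels from the source batch and transfers to the target.
    Ships the accompanying evaluation protocols (subsampled MMD with in-batch
    baseline, accuracy/F-score/AUC/MCC, subject-level median ensembling,
    label-permutation null), a bootstrap selection-frequency biomarker screen,
    a two-batch synthetic data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
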