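Package: guidepred
Title: Sequence-Based Prediction of CRISPR/Cas9 sgRNA On-Target Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts on-target cleavage activity of CRISPR/Cas9 single-guide
    RNAs from their 30-nucleotide genomic context. Encodes each guide as a
    deterministic, named vector of 9632 features: position-specific k-mer
    indicators (k = 1..4), position-independent k-mer counts (k = 1..4),
    RNA secondary-structure thermodynamics (minimum free energy and specific
    heat via the ViennaRNA command-line tools), and two assay covariates.
    Features are ranked by repeated random-forest Mean Decrease Gini
    importance, filtered by an importance threshold and a single-pass ANOVA
    redundancy test, and scored with a linear-kernel support vector
    regression. Evaluation uses leave-one-gene-out cross-validation with
    ROC, precision-recall, sensitivity-specificity and MCC threshold curves
    plus RMSE. A synthetic-guide simulator with planted sequence effects
    provides ground truth for end-to-end validation, and a command-line
    interface wires the stages into a pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    pROC,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
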