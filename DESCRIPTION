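Package: ddiprofiler
Title: Drug-Drug Interaction Effect Prediction from Similarity Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the pharmacological effect type of drug-drug
    interactions (DDIs) from three per-drug similarity profiles: structural
    similarity (Tanimoto coefficients between molecular fingerprints),
    target-gene similarity (shortest-path statistics on a functional
    interaction network), and Gene Ontology term similarity (the same
    statistic on the GO graph). Each profile pair is reduced by an
    autoencoder whose encoder is trained jointly with a deep feed-forward
    multi-label classifier, minimizing the sum of the reconstruction and
    classification costs. Includes the evaluation protocol (dataset
    filtering, stratified k-fold cross-validation, PCA/SVM/random-forest
    baselines, macro/micro metrics and precision-recall curves, a
    novel-interaction report) and a seeded synthetic-world generator so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ChemmineOB,
    ChemmineR,
    e1071,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
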