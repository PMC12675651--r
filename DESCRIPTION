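Package: septaphen
Title: Clinical Sepsis Phenotyping, Trajectories and Proteome-Informed Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives clinical sepsis phenotypes from routine ICU data by
    principal component analysis and k-means clustering with silhouette-based
    selection of the cluster number, tracks patients' phenotype trajectories
    across ICU days by frozen-parameter projection onto the day-1 model,
    screens plasma-proteome intensity matrices for phenotype-associated
    proteins (batch median normalization, ANOVA with Benjamini-Hochberg
    correction and Tukey post-hoc tests), and trains compact random-forest
    classifiers with nested Monte Carlo cross-validation, Shapley-value
    feature ranking, minority-class bootstrap rebalancing and knee-point
    selection of the feature count. A synthetic-cohort generator with ground
    truth labels makes every stage testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    ranger,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
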