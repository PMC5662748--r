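Package: pbdsn
Title: Differential Sub-Network Analysis of Pairwise Feature Ratios
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds signed Pearson-correlation networks over pairwise
    feature ratios for each sample group or time point of an omics
    abundance matrix, extracts the differential sub-network whose edges
    disappear or flip sign in most other groups (or earlier time points),
    and ranks its hub vertices by degree as candidate ratio biomarkers.
    Includes minimum-value imputation, fold-change feature filtering, a
    feature-level network variant, logistic-regression ROC/AUC evaluation
    of selected ratios, per-group mean +/- standard-error summaries, a
    synthetic-data generator with planted differential correlation hubs,
    and an end-to-end pipeline with deterministic text outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, Metabolomics, GeneExpression,
    DifferentialExpression, Classification
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'data-io.R'
    'differential.R'
    'evaluation.R'
    'network.R'
    'pbdsn-package.R'
    'pipeline.R'
    'preprocess.R'
    'ranking.R'
    'ratios.R'
    'synthetic.R'
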