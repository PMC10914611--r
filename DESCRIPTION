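Package: connCPM
Title: Connectome-Based Predictive Modeling of Continuous Phenotypes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts continuous phenotypes from structural (streamline-count)
    connectomes via connectome-based predictive modeling (CPM) with repeated
    k-fold cross-validation. Implements consistency filtering of edges, signed
    edge selection by covariate-adjusted partial Spearman correlation,
    network-strength summarisation, linear prediction models, per-edge
    selection-stability maps, permutation tests for model performance and edge
    stability, and permutation tests for the overlap of two phenotypes' stable
    networks. Ships a synthetic-data generator that emulates the statistical
    structure of a two-site questionnaire-plus-connectome cohort (skewed
    anticorrelated phenotypes, over-dispersed streamline counts, planted
    signed edge-phenotype couplings) so the full pipeline runs end to end
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Network, GraphAndNetwork, Regression, StatisticalMethod
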