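Package: lesionhub
Title: Predicting Functional Brain Network Topology from Multivariate Lesion Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate lesion-network modelling for the human functional
    connectome. Builds binary functional networks from Fisher-z connectivity
    matrices across sparsity thresholds, computes small-world and efficiency
    topology (global efficiency, local efficiency, sigma against degree-matched
    rewired null networks), fits linear support vector regression models that
    predict network topology from node-wise lesion percentages with
    leave-one-out cross-validation and permutation inference, detects "lesion
    hubs" from significant feature weights and classifies their effect as
    integrating or segregating, and relates them to healthy-connectome hubs via
    participation coefficient, within-module degree and nodal efficiency. A
    synthetic cohort generator with a planted lesion-to-topology coupling makes
    the full pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    RNifti,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
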