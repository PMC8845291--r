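Package: rbndegen
Title: Information-Theoretic Degeneracy in Random Boolean Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Generates random Boolean networks with gene-regulatory wiring
    statistics (10 nodes, 1-2 inputs per node, randomly assigned logic
    operators), applies systematic type-1 (incoming) and type-2
    (incoming + outgoing) edge lesions, simulates synchronous discrete
    dynamics with bit-flip perturbations as well as continuous
    stochastic-differential-equation gene expression dynamics derived from
    the Boolean rules, and quantifies degeneracy and partial degeneracy of
    node subsets with respect to a random output sheet using plug-in
    Shannon entropy and mutual information on binary time series.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
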