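Package: ontorank
Title: Ontology-Graph Embeddings and Learning-to-Rank Gene-Disease Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts ontology axioms and entity annotations into a labeled
    graph, embeds every node with edge-label-aware random walks and skip-gram
    training, and ranks candidate genes for diseases with a pointwise
    two-tower neural learning-to-rank model. Includes annotation filters
    (evidence-code exclusion, expression thresholding, interaction-confidence
    cutoffs, ortholog mapping), macro-averaged ROC and Hits-at-n evaluation
    with disease-wise cross-validation, and a synthetic planted benchmark for
    end-to-end validation without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
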