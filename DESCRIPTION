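Package: topicflow
Title: Temporal Topic Evolution in Longitudinal Document Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models complex temporal topic evolution in longitudinal text
    corpora such as the biomedical literature. The corpus is discretized into
    contiguous (optionally overlapping) epochs, each epoch's topics are
    discovered with a hierarchical Dirichlet process mixture fitted by Gibbs
    sampling, and topics in adjacent epochs are linked in a temporal
    relatedness graph weighted by the Bhattacharyya distance and the
    directed Kullback-Leibler divergence. Automatic CDF-based pruning at a
    single user-set operating point yields sparse graphs from which topic
    emergence, disappearance, gradual evolution, speciation, convergence,
    splitting and merging are classified. A synthetic-corpus generator
    plants each of these phenomena with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    jsonlite,
    yaml,
    igraph,
    ggplot2,
    generics,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
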