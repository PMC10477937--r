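Package: clustann
Title: Cluster-Level Reference-Based Cell-Type Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfers cell-type labels from an annotated reference
    single-cell dataset to the clusters of a query dataset. Query and
    reference are compared at the cluster level through Pearson
    correlations of marker-gene expression, calibrated against a broad
    background atlas: an adaptive correlation cutoff is estimated by
    decomposing the pooled query-background correlation distribution
    into one to three Gaussian components, and ambiguous matches are
    resolved with one-sided Wilcoxon rank-sum tests on sub-cluster
    marker genes. Includes tools to build reference bundles from
    annotated count matrices, a negative-binomial scenario simulator
    with ground truth, a six-outcome evaluation framework, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
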