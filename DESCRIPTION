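Package: dcnet
Title: Differential Co-Expression and Differential Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers differential co-expression networks and pathway-level
    differential gene regulatory networks between two sample conditions.
    Gene-pair association changes are scored with two differential metrics,
    the absolute difference in co-expression and the degree of association
    shift, using Pearson, Spearman or a signed normalized mutual information
    measure. Significance is assessed against a single pooled permutation
    background model shared by all tested edges, with Benjamini-Hochberg
    multiple-testing correction. Also ships a benchmarking framework that
    simulates expression data from a tree-shaped transcription-factor/target
    network via a graph-derived covariance, injects case-group perturbations
    (knockdown, differential expression, correlation inversion, loss of
    co-expression), and scores recovered networks against the ground truth
    with the Matthews correlation coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
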