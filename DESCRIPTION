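Package: calcgraph
Title: Graph-Based Classification of Mammographic Calcification Distribution Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, interpretable pipeline for classifying the spatial
    distribution of mammographic microcalcifications into the five BI-RADS
    descriptors (diffuse, regional, grouped, linear, segmental). Calcifications
    are detected by white top-hat morphological filtering with an optional
    patch-verifier convolutional network, converted into a calcification graph
    (deep patch features fused with learnable spatial embeddings, k-nearest-
    neighbour adjacency, geometric edge labels), and classified with an
    edge-conditioned graph convolutional network trained under focal loss.
    Per-node gradient-based saliency maps explain each prediction. A synthetic
    mammogram phantom generator with exact ground truth supports development
    and testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    tiff,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
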