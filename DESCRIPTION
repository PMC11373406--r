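Package: urfclust
Title: Unsupervised and Federated Random Forest Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Patient stratification by unsupervised random forests. Trees are
    grown without labels using a Fixation-Index-inspired splitting rule that
    contrasts within-child and between-child spread of a candidate feature;
    leaf co-occurrence across the forest yields a sample affinity matrix that
    is clustered with Ward linkage. Supports late fusion of several omics
    layers by summing leaf co-occurrence counts, privacy-preserving federated
    learning by concatenating serialized client forests, cluster-specific
    feature importance computed one-vs-all along the already-grown splits,
    cluster number selection by silhouette or tree-count stability, and
    generators for two-dimensional benchmark scenarios (globular clusters,
    outliers, varying sizes, concentric rings).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    cluster,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
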