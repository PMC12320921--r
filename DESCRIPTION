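Package: scfcpls
Title: Signed Network Metrics and Partial Least Squares for Longitudinal
    Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Graph-theoretic analysis of paired structural (SC) and
    functional (FC) brain connectivity matrices, and partial least squares
    (PLS) correlation analysis linking regional network metrics to
    behavior.  Provides matrix ingestion and normalization (streamline
    proportion scaling, Fisher z transform, consensus thresholding),
    signed weighted graph metrics (Louvain modularity with asymmetric
    treatment of negative weights, positive and signed local clustering,
    weighted degree), degree- and weight-preserving null models for
    signed networks, regional SC-FC coupling, mean-centered and
    behavioral PLS with permutation, bootstrap, test-train and split-half
    reproducibility machinery, cohort quality-control statistics
    (connectome fingerprinting, QC-FC, exclusion ledgers, panel PCA), and
    a synthetic two-timepoint cohort generator with planted effects for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
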