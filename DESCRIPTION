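Package: hetmda
Title: Metapath-Guided Heterogeneous-Network Link Prediction for
    miRNA-Disease Associations
Version: 0.1.0
Authors@R:
    person("hetmda", "maintainers", email = "hetmda@example.org",
           role = c("aut", "cre"))
Description: Predicts miRNA-disease associations by link prediction on a
    typed biological heterogeneous network (miRNA, disease, mRNA, lncRNA,
    circRNA, protein, drug, microbe).  Implements relational graph
    convolution pre-encoding, enumeration and sampling of node-specific and
    common metapaths, attention-based semantic aggregation, and a decoder
    in which common-metapath structural features guide feature pooling.
    Splits, negative sampling and metapath materialization are constructed
    under a strict leakage-safe protocol: validation and test edges never
    enter the training graph, and no metapath instance serving a candidate
    pair may traverse the candidate edge itself.  Ships a seeded
    stochastic-block-model generator of schema-conforming synthetic
    networks with planted, metapath-mediated association structure so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
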