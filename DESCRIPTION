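Package: pathograph
Title: Disease-Specific Variant Pathogenicity Prediction on Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts disease-specific pathogenicity of genetic variants as link
    prediction on a heterogeneous biomedical knowledge graph. Provides a typed
    multigraph store with the augmentation rules needed to integrate variants
    (protein-node splitting, variant attachment, transient/permanent typing of
    protein-protein interactions from time-course co-expression, tissue
    co-expression binning, and edge masking against label leakage), deterministic
    extraction of fixed-length alternative-allele genomic context windows for
    SNVs, insertions, deletions and indels, pluggable node-embedding providers
    with a deterministic feature-hashing embedder, a two-layer graph
    convolutional encoder with a feed-forward pair decoder trained end-to-end by
    stochastic gradient descent, per-gene class-balanced and date-based data
    splits, evaluation statistics (balanced accuracy, Wilson score intervals,
    exact binomial test, bootstrap), and seeded synthetic-data generators with a
    tunable planted variant-disease signal so the whole pipeline is testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
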