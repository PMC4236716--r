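Package: spanet
Title: Seed-Guided Protein Network Reconstruction, Centrality Tuning and
    Module Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nominates phenotype-associated candidate genes from
    protein-protein interaction data. Reconstructs a Gene Ontology
    constrained subnetwork around a set of literature-curated seed
    proteins (the selective permissibility algorithm), statistically
    tunes it by testing each node's eigenvector centrality against a
    degree-preserving random-network ensemble, decomposes the tuned
    network into dense modules (MCODE), scores module enrichment for
    biological-process terms by hypergeometric tests with
    Benjamini-Hochberg correction, extracts unknown-function candidate
    proteins, and identifies reporter transcription factors by
    integrating a regulatory network with gene-level expression
    p-values. Includes readers for BioGRID TAB 2.0 and GAF 2.x files
    and a synthetic-benchmark generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    Matrix,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
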