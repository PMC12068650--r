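Package: hmglearn
Title: Knowledge-Enhanced Heterogeneous Molecular Graph Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds three-view heterogeneous molecular graphs (molecule,
    element, drug) from SMILES strings and two knowledge graphs, encodes
    them with a dual node-edge message-passing graph transformer, and
    pre-trains the encoder with a cross-view contrastive objective that
    tolerates imbalanced view sizes. Includes BRICS fragmentation,
    SMARTS functional-group matching against an elemental knowledge
    graph, a drug-aware constrained-clustering mini-batch generator,
    fine-tuning heads for molecular property and drug-drug interaction
    prediction, and synthetic fixture generators so the full stack is
    testable at desk scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
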