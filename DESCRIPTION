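Package: gostar
Title: Protein Function Prediction from Sequence, Domains and
    Interaction Neighborhoods with n-Star Consensus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts Gene Ontology (GO) terms for target proteins by
    combining three orthogonal predictors run on the target's pruned and
    filtered level-2 protein-protein interaction neighborhood: clustering
    of neighbors in a seven-dimensional physico-chemical property space,
    frequency ranking of GO terms reached through validated domain-domain
    interactions, and Fisher exact enrichment of neighborhood annotations.
    Predictions are merged with an n-star consensus (a term is accepted
    when at least n predictors propose it) and evaluated with
    precision/recall/F and CAFA-style Fmax. A synthetic-world generator
    with planted modular structure makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
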