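Package: herbnet
Title: Graph Neural Networks and Network Proximity for Herbal Formula Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for interpreting multi-herb formulas under traditional
    herbal theory. Builds one-hot herb feature matrices from Qi, Flavor,
    Meridian and syndrome annotations, constructs herb co-prescription
    graphs, and fits a graph attention network for multi-label herb-disease
    prediction and an enclosing-subgraph (SEAL-style) classifier for
    herb-herb combination prediction. A perturbation-weighted
    protein-protein interaction model links herb ingredient targets to
    drug-perturbation signature genes through weighted shortest-path
    proximity, with Fisher-exact and t-test enrichment over theory groups,
    and a tissue-expression module quantifies alignment between meridian
    annotations and signature-gene expression. A synthetic-data generator
    with planted structure makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
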