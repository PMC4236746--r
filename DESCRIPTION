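Package: keypathways
Title: De Novo Extraction of Key Pathways from Interaction Networks and
    Multi-Omics Indicator Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts maximal connected sub-networks ("key pathways") from an
    undirected biological interaction network in which all nodes but at most K
    are active, where per-gene activity is derived from one or more binary
    gene-by-case indicator matrices via per-matrix case-exception thresholds
    (L) combined through a boolean formula (AND/OR/XOR). Provides an exact
    branch-and-bound enumerator for small instances, a multi-start greedy
    expansion and an ant-colony-optimization heuristic for large networks,
    positive/negative node lists to bias the search, a (K, L) parameter sweep
    with per-node appearance scores for visualization, readers and writers for
    SIF/edge-list networks, TSV indicator matrices, GraphML/JSON/TSV results,
    and a synthetic-fixture generator with planted active modules.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
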