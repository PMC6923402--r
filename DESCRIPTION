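Package: topcontrol
Title: Candidate Disease-Gene Prioritization from TF-miRNA Co-Regulatory
    Network Controllability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Prioritizes candidate disease genes and miRNAs without prior
    disease knowledge by layering differential expression on a typed
    TF-miRNA co-regulatory network and scoring nodes by three network
    controllability roles: hub-degree nodes (top decile of degree), members
    of a minimum dominating set (exact branch-and-bound or greedy), and
    members of a minimum connected dominating set of the largest connected
    component (growth-and-prune heuristic). Nodes are ranked by the number
    of roles they carry and, within equal score, by absolute log2 fold
    change. Candidate layers are evaluated against user-supplied disease
    annotations with confusion-matrix metrics and an upper-tail
    hypergeometric test over the network background. Includes readers and
    writers for typed edge lists, expression tables and annotation lists, a
    deterministic synthetic-data generator with planted ground truth, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
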