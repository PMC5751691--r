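Package: nwsteiner
Title: Node-Weighted Steiner Trees for Signaling-Pathway Subnetwork Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies candidate elements of signaling pathways in large
    protein-protein interaction networks by solving a node-weighted Steiner
    tree problem. Interaction confidence scores are transformed into edge
    costs, proteins receive degree-based negative node weights, and pathway
    source/terminal proteins become compulsory terminals. Instances are
    shrunk with two degree-1 reduction tests, solved with a modified
    unrooted Goemans-Williamson moat-growing heuristic followed by strong
    pruning, and the resulting subnetwork is scored with source-to-terminal
    betweenness degrees to select important proteins and interactions.
    Includes a curated PI3K/Akt-MAPK reference subnetwork, a synthetic
    instance generator, and brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
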