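Package: bnscreen
Title: Screening Boolean Network Models for Low-Connectivity, High-Impact Intervention Targets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Screens Boolean network models of gene regulation for candidate
    intervention targets using only the logical rules and the interaction
    graph, avoiding the exponential state space. Nodes are scored by vertex
    betweenness and by determinative power (a sum of mutual-information values
    under a binary Shannon entropy), ranked against z-transformed connectivity,
    and classified into gatekeepers (selected nodes ranking higher on the
    static measures than on connectivity), selected non-gatekeepers, and
    non-selected nodes. Models are read and written in the BoolNet plain-text
    rule format and in SBML Level 3 qual (restricted to Boolean species). An
    exhaustive synchronous attractor engine for small networks provides
    knockout and overexpression perturbation metrics (attractors lost, new
    attractors, minimal Hamming distances) as dynamic ground truth, together
    with a random network generator, curated fixtures, and report export to
    TSV, JSON, DOT, and GraphML.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
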