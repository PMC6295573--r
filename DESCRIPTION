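Package: morphnet
Title: Individual Morphological Brain Networks and Weighted Graph Analysis
Version: 0.1.0
Authors@R:
    person("Morphnet", "Developers", email = "morphnet@example.org",
           role = c("aut", "cre"))
Description: Builds individual morphological brain networks by correlating
    multi-feature regional morphometry vectors (cortical thickness, gray-matter
    volume, surface area, mean curvature, fold index) over the 68-region
    Desikan-Killiany parcellation, one fully weighted 68-node network per
    subject. Computes weighted graph-theory measures (Latora-Marchiori global
    efficiency, Rubinov-Sporns local efficiency, Brandes betweenness
    centrality, Newman modularity via best-of-rounds Louvain), identifies
    per-subject and group-consensus hubs, performs edge-wise two-group
    inference with rank transformation, Levene-gated t-tests and
    Benjamini-Hochberg FDR, classifies edge changes, and screens subjects by
    combining Mini Mental State Examination scores with network properties.
    Includes a synthetic cohort generator with implantable edge effects so the
    whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
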