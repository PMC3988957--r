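Package: mlinet
Title: Motif and Null-Model Analysis of Electrical and Chemical Interneuron Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Connectivity analysis for multi-patch-clamp recordings of cerebellar
    molecular layer interneurons. Provides triad motif censuses for undirected
    (electrical, gap-junction) and directed (chemical, GABAergic) networks, a
    transitivity taxonomy of directed triads, clustering and anticlustering
    coefficients of recorded subnetworks, uniform and distance-dependent Monte
    Carlo null models with Bonferroni-corrected significance tests,
    common-neighbor analysis of the overlap between the two networks, IPSC
    cross-correlogram synchrony, molecular-layer position statistics for
    feedforward motifs, and a synthetic-data generator emulating the geometry
    and wiring statistics of local multi-cell recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
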