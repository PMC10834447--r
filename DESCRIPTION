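Package: lrrscape
Title: Architecture, Motif, and Expansion Analysis of Plant Cell-Surface Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of plant receptor-like kinases
    (RLKs) and receptor-like proteins (RLPs) from protein sequences.
    Classifies proteins by transmembrane and kinase-domain content, parses
    leucine-rich-repeat (LRR) ectodomain architecture including N-loopout and
    island-domain insertions and the island-domain-plus-four-LRR arrangement,
    scans juxtamembrane and transmembrane regions for diagnostic motifs
    (Kx5Y, Yx8KG, QxxT/S, GxxxG) and charge, computes lineage-median
    gene-family expansion rates with Mantel, Fisher, and FDR statistics, and
    clusters island domains from sequence-similarity trees via cophenetic
    distances and Louvain communities. Includes a seeded synthetic-proteome
    generator with machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
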