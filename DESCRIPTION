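Package: pantree
Title: Pan-Genome Trees from Gene Family Presence/Absence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds pan-genome trees for closely related microbial genomes.
    Protein sequences are grouped into gene families from all-vs-all BLAST
    tabular hits by a reciprocal 50% coverage / 50% identity rule, gene
    family presence/absence is collected in a binary pan-matrix, distances
    between genome profiles are computed as weighted relative Manhattan
    distances (with core/shell/cloud occupancy weighting schemes) or as
    Jaccard distances, and rooted ultrametric trees are produced by UPGMA
    with bootstrap supports obtained by resampling pan-matrix columns.
    Includes a simulator of pan-matrices with planted core/shell/cloud
    structure, gene gain/loss along a known tree, and mock alignment tables,
    plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ape,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
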