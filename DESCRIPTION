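Package: plastrep
Title: Plastome Repeat Architecture, Dispersion Statistics, and Inversion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Tools for analysing the repeat architecture of plastid genomes and
    its relationship to large structural inversions. Discovers dispersed and
    tandem repeats within circular plastomes, merges and groups them, clusters
    repeat families across taxa with a Markov Cluster implementation, tests the
    spatial dispersion of repeats in genomic windows against a Poisson null with
    two-tailed Pearson chi-square tests, detects large inversions from
    maximal-unique-match anchors with exact endpoint refinement, characterises
    microhomology and short inverted-repeat geometry at inversion endpoints, and
    fits Pagel's lambda, PGLS regressions, and phylogenetic t-tests to
    log-transformed repeat traits on a fixed phylogeny. A synthetic plastome
    generator with planted repeat families, controlled spatial dispersion,
    Brownian-motion traits, and constructive inversion scenarios provides known
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    igraph,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    nlme,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
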