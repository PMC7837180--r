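Package: phylocore
Title: Core-Proteome Phylogenomics for Bacterial Strain Placement
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of the core-proteome supermatrix
    phylogenomics workflow used to place bacterial strains within a species
    group: reference-anchored reciprocal-best-hit ortholog extraction with
    affine-gap Smith-Waterman scoring and Karlin-Altschul E-values,
    progressive multiple alignment of each ortholog group, column-wise
    concatenation into a protein super-alignment, conserved-block filtering
    with Gblocks-style default parameters, Kimura-corrected protein distances,
    neighbor-joining tree inference with bootstrap bipartition support, and
    Newick export. Also provides genome-composition summaries (GC content and
    windowed GC skew) and a seedable proteome-evolution simulator that evolves
    single-copy core genes plus lineage-specific decoy genes along a known
    tree, so every stage of the pipeline is testable against ground truth.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
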