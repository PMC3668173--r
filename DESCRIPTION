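Package: polyhap
Title: SNP and Haplotype Analysis of Polyploid Amplicon Clone Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of cloned PCR amplicons from autopolyploid genomes:
    simulation of octoploid clone libraries with known haplotype truth
    (including PCR template-switching chimeras and per-base error), global
    alignment of clones to reference fragments, clone-support filtered SNP
    calling with intron/exon classification, SNP-density and cross-species
    shared-SNP summaries, haplotype inference and cross-species consensus
    haplotype analysis, deduced protein variants with molecular mass and
    isoelectric point, Nei-Gojobori dN/dS with Jukes-Cantor correction, and
    neighbor-joining phylogenies with bootstrap support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
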