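Package: IGEmapper
Title: Precise Comparative-Genomic Mapping of Integrative Genetic Elements
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps integrative genetic elements (prophages, ICEs and related
    mobile DNA) in prokaryotic genomes by a two-phase ("ping-pong")
    comparative-genomic alignment strategy seeded at integrase genes, based on
    the principle that the int-attP integration module is cohesive. Locates
    attL, attR and attB precisely, counts uninterrupted reference genomes as
    comparative support, controls insertion-sequence artifacts, scores false
    positives with seven compositional and gene-content metrics and a trainable
    linear model, resolves tandem element arrays, deduplicates vertically
    inherited elements by fragment average nucleotide identity, subtypes
    elements as phage or ICE from HMM content, tests target genes for Pfam
    domain disruption without restoration, and screens integrase phylogenies
    for site-promiscuous clades and candidate cases of regulated gene
    integrity. Includes a deterministic synthetic-genome fixture generator and
    an internal alignment engine so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph,
    ape,
    phangorn,
    mgcv,
    pROC
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
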