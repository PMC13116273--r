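Package: mitocomp
Title: Comparative Architecture Analysis of Annotated Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative analysis of annotated animal mitochondrial
    genomes: whole-genome, per-gene and sliding-window nucleotide skew
    landscapes with GC-skew regime classification; circular signed gene-order
    representation, breakpoint distances, localization of rearranged segments
    and parsimony-based ancestral gene-order inference rooted by an outgroup;
    tRNA repertoire scoring against the canonical 22-tRNA complement and
    detection of conserved tRNA gene clusters; relative synonymous codon usage
    (RSCU) under the invertebrate mitochondrial genetic code with principal
    component analysis. Includes a deterministic generator of annotated
    velvet-worm-like mitogenomes with recorded ground truth for validating
    every analysis stage, and GenBank flat-file, FASTA and feature-table I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
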