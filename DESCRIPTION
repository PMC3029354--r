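Package: intronsites
Title: Intron Insertion-Site Mapping, Hot Spots and Sequence-Similar
    Intron Pairs in Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of spliceosomal intron positions
    across a gene family. Reconstructs coding gene structure from GFF3 and
    FASTA, extracts CDS-interrupting introns with codon phase and anchor
    residue, projects insertion sites onto a protein multiple alignment,
    builds per-family presence matrices, detects clade-level intron hot spots
    with an exact fractional-share rule, and identifies sequence-similar
    intron pairs by Smith-Waterman local alignment with a shuffle-based
    extreme-value significance test. Includes a synthetic-data generator that
    plants insertion sites, paralogs and homologous intron sequences on a
    clade structure with full truth tables, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
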