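Package: gblscreen
Title: Degenerate PCR Screen Design for Gamma-Butyrolactone Regulatory
    Systems in Streptomyces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs and evaluates degenerate PCR primer screens for
    collocated, divergently oriented autoregulator synthase/receptor gene
    pairs (ScbA/ScbR homologues) in high-GC Streptomyces genomes. Reads
    annotated genomes (GenBank flat file or GFF3+FASTA), finds homologue
    pairs within a maximum intergenic distance and classifies their
    orientation, profiles per-column conservation of aligned homologues to
    pick primer anchor motifs, back-translates anchor contexts into IUPAC
    degenerate primers with a codon usage table, predicts amplicons by
    3'-aware degenerate primer matching, classifies priming likelihood of
    binding-site variants, and discovers palindromic autoregulatory
    response elements in amplified intergenic regions with a ZOOPS EM
    motif finder. Includes a synthetic fixture generator that plants gene
    pairs, motif variants and palindromic operators with machine-readable
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
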