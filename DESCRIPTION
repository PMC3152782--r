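Package: denovotx
Title: De Novo Assembly of Stranded RNA-Seq Reads into Transcript Contigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reference-genome-independent transcriptome assembly pipeline
    for short stranded and non-stranded RNA-Seq reads. Reads are dereplicated
    and cleaned with a rare k-mer filter, assembled with an internal de Bruijn
    graph assembler across a ladder of k values, merged into a non-redundant
    contig set by greedy dovetail overlap layout, then split, oriented and
    polished using strand-specific read coverage so that overlapping antisense
    transcripts are resolved into separate sense-strand contigs. Includes a
    four-criterion assembly evaluator (accuracy, completeness, contiguity,
    gene fusions) against a reference genome and gene annotation, and a
    synthetic transcriptome/read simulator with full ground truth for testing
    every stage without real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    withr,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
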