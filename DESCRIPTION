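Package: txcascade
Title: Iterative Homology Assignment, Consensus Building and Marker
    Discovery for De Novo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Annotates de novo transcriptome assemblies (contigs and
    singleton reads) by an ordered cascade of similarity searches against
    reference databases (mitochondrial genome, non-coding RNA, coding
    transcripts, EST clusters, genomic sequence, cross-species
    consensuses), then builds reference-anchored majority-consensus
    sequences from the assigned reads.  Includes read preprocessing
    (adaptor excision with in-read splitting, polyA and quality trimming,
    low-complexity masking), a self-contained seed-and-extend local
    similarity search engine with a BLAST-tabular adapter, microsatellite
    discovery with compound merging, pileup-based SNP/indel calling with a
    minor-allele depth rule, transition/transversion and codon-position
    classification against an annotated mitochondrial reference, and
    construction of partitioned phylogenomic amino-acid supermatrices with
    hybrid taxa, gap-column trimming and paralog filtering.  A seedable
    synthetic-data generator makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
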