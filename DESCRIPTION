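Package: cubscan
Title: Genome-Wide Codon Usage Bias Scanning and Functional Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide codon usage bias (CUB) analysis of coding
    sequences. Scores each gene by differential entropy against a synonymous
    re-encoding null, cross-validates with Wright's effective number of codons
    (ENC), builds genome-wide codon usage tables and preferred-codon calls,
    profiles GC content over genes and their flanks, runs minimum-hypergeometric
    (mHG) ranked-list functional enrichment with exact p-values, compares
    per-gene bias between genomes over ortholog maps, and screens pairwise
    alignments for pseudogene lesions (frameshifts and premature stop codons).
    Includes a synthetic-genome simulator with planted bias and planted gene
    sets so every stage of the pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
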