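Package: ampkit
Title: Functional-Gene Amplicon Processing, Error Profiling, and
    Memory-Constrained OTU Clustering
Version: 0.1.0
Authors@R: person("ampkit", "developers", role = c("aut", "cre"),
    email = "ampkit@example.org")
Description: A desk-scale toolkit for functional-gene amplicon surveys:
    tag (MID) demultiplexing with ordered quality filtering (degenerate
    primer matching, ambiguous-base, length, and read-quality rQ filters),
    exact-duplicate dereplication with id/sample mappings, defined
    (mock) community sequencing-error profiling by global alignment with
    homopolymer context, streaming thin/thick-edge agglomerative OTU
    clustering under a memory budget with single, complete, and average
    linkage, least-squares representative sequence selection, alpha and
    beta diversity estimation (rarefaction, Shannon, Chao1,
    Chao-abundance-corrected Jaccard and Sorensen, UPGMA dendrograms),
    degenerate oligonucleotide probe matching, and a seeded mock-community
    read simulator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Biostrings
Config/testthat/edition: 3
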