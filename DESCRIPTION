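Package: polytractr
Title: Census and Locational Enrichment Analysis of Perfect Short Tandem
    Repeats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exhaustive identification of perfect mono-, di- and
    tri-nucleotide tandem repeats (polytracts) in any reference genome,
    canonicalization of repeat units into strand- and phase-symmetric
    species groups, detection of single-nucleotide hinge sites between
    tandem repeats, and adjacency extension of repeat territory.
    Provides exact binomial and hypergeometric tests for over- and
    under-representation of arbitrary genomic features within repeat
    territory, relative risk with Katz 95% confidence intervals,
    Bonferroni control for feature landscapes, Kolmogorov-Smirnov
    length-distribution comparisons with hierarchical clustering, and
    genomic region annotation of repeats from Ensembl GTF gene models.
    Includes a synthetic-genome simulator with planted repeats and
    controlled feature enrichment so every statistic is testable without
    external downloads, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
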