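Package: codonscout
Title: Homolog Retrieval, Diversity-Constrained Selection and
    Comparative Coding-Region Detection for Single Nucleotide Queries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An offline, testable pipeline that turns a single nucleotide
    query into comparative coding-potential predictions. Homologs are
    retrieved through a pluggable search backend with an iterative
    word-size schedule and taxonomic widening, reduced to a
    diversity-constrained representative set by density-based clustering
    on Smith-Waterman percent distances, aligned and scored through
    external-tool adapters, and the resulting high-scoring coding
    segments (HSS) are merged, filtered and exported as TSV, BED6, GFF3
    and protein FASTA. Long queries are subdivided into overlapping
    windows searched against a temporary query-specific database. A
    synthetic sequence-family generator and a word-size-aware mock
    search backend make every stage reproducible without network access
    or external binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
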