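Package: txome
Title: Transcriptome Object Models, Sorted Genomic Iterators and Overlap
    Annotation for Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building custom transcriptomics analyses: immutable
    genomic intervals with a reference-dictionary (RefDict) model of chromosome
    order and lengths; a Transcriptome container parsed from GTF/GFF3 with
    explicit gene/transcript/exon/intron/CDS/UTR hierarchy, lazy spliced and
    translated sequence slicing, and an external annotation store; a uniform
    family of sorted, optionally random-access iterators over BED, bedGraph,
    GFF3/GTF, VCF, SAM/BAM and FASTA with grouping, tiling, merging and a
    single-pass overlap-join (annotation) iterator; exporters to BED, GFF3 and
    tidy tables; command-line style tools for nucleotide mismatch profiles and
    T-to-C conversion annotation; and a deterministic synthetic fixture
    generator used by the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
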