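Package: trbkit
Title: Annotation and Expressed-Repertoire Analysis of Duplicated T Cell
    Receptor Beta Loci
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Germline mining, classification and naming of T cell receptor
    beta (TRB) V, D, J and C segments from genomic sequence; neighbor-joining
    phylogenetics with bootstrap support for segment-family verification;
    paired-end amplicon processing (quality trimming, primer demultiplexing,
    read merging, collapsing, open-reading-frame filtering and germline
    assignment); CDR3 junction decomposition into templated and non-templated
    regions; and a ground-truthed simulator of duplicated dual-orientation
    TRB loci and recombined amplicon reads for end-to-end validation.
    Designed around the duplicated salmonid TRB regions that arose from the
    salmonid-specific whole-genome duplication.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    tibble,
    dplyr,
    yaml,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
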