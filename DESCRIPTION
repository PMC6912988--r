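Package: spliceflow
Title: Reference-Guided Transcriptome Assembly from Short and Long RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles spliced RNA-seq read alignments (SAM) into transcripts
    using a per-locus splice graph with iterative heaviest-path extraction and
    EM-based coverage estimation. Includes spurious spliced-alignment filters,
    sparse bit-vector path encodings of reads and transcripts, a long-read mode
    with splice-site correction against low-error support and support-ordered
    graph pruning, super-read construction from short reads via k-unitigs with
    EM coverage assignment, transcript- and intron-level accuracy metrics, and
    a deterministic synthetic-data generator for multi-isoform loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicAlignments,
    GenomicRanges,
    ggplot2,
    IRanges,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
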