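Package: isoamp
Title: Isoform Annotation and Quantification for Long-Read Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates and quantifies full-length transcript isoforms of a
    single gene from long-read (nanopore) cDNA amplicon sequencing. Builds a
    metagene (exon concatenation) reference from a GTF/GFF3 annotation,
    ingests spliced alignments (SAM/BAM, PSL, MAF) or aligns reads with a
    built-in banded spliced aligner, mines alignment insertions for novel
    exons, builds a canonical splice-junction catalogue from error-free
    genome alignments and corrects noisy junction breakpoints, collapses
    read exon chains into a unique isoform set with abundance filters,
    quantifies isoforms with multi-compatibility down-weighting and TMM
    normalisation, and classifies the predicted coding impact of each
    isoform (reading-frame maintenance, premature stops, in-frame
    insertions and deletions in protein coordinates). A bundled simulator
    generates a synthetic locus and noisy full-length reads with complete
    ground truth so every pipeline stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    edgeR,
    jsonlite,
    stats,
    utils,
    methods,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
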