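Package: cobindkit
Title: Co-Binding Analysis of Protein-Nucleic Acid Peak Sets
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares peak-called protein-DNA and protein-RNA binding
    datasets (ChIP-seq, CUT&RUN, eCLIP BED files). Screens many datasets at
    once by binning the genome and computing an asymmetric co-binding
    correlation matrix; performs scoped pairwise overlap analysis between a
    reference and an experimental peak set, classifying every event as a
    complete overlap, 5' partial, 3' partial or proximal peak and
    aggregating binding profiles around reference-peak midpoints, with
    optional gene (GTF) and sequence (FASTA) annotation; compares two
    completed runs to report condition-unique and shared overlap loci; and
    simulates peak sets with planted co-binding structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    grDevices,
    graphics,
    jsonlite,
    pheatmap,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
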