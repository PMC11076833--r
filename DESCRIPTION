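Package: svlook
Title: IGV-Style Visualization and Force-Calling of Structural Variants
    from Long-Read BAM Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts structural-variant (SV) evidence from long-read
    (PacBio/ONT) BAM alignments by combining CIGAR-derived events with
    split-read breakpoints, classifies the SV structure carried by each
    read (DEL/INS/DUP/INV/TRA), lays reads out for IGV-style static
    figures via greedy non-overlapping interval scheduling, and
    force-calls genotypes for candidate SVs supplied as VCF or BED using
    allele-frequency thresholds. Ships a deterministic simulator that
    writes reference FASTA, truth VCF and aligned BAM fixtures with
    implanted SVs of known genotype, plus a five-subcommand command-line
    interface for batch figure generation and genotyping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    jsonlite,
    parallel,
    stats,
    utils,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    GenomicAlignments,
    BiocGenerics,
    S4Vectors,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
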