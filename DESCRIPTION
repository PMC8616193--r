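Package: armiR
Title: Arm-Reference Construction and Hierarchical isomiR Classification
    for Small RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds custom miRNA arm references (mature sequences extended
    by templated flanking nucleotides from precursors or genome
    coordinates), aligns small RNA-seq reads with zero mismatches,
    classifies reads hierarchically into reference miRNAs, template
    isomiRs and 3' non-template isomiRs with an explicit offset
    nomenclature, exports DESeq2/edgeR-ready count matrices, filters
    external differential-expression tables, and renders profile and DE
    reports. Includes a deterministic synthetic-data generator with
    planted isomiR composition for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
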