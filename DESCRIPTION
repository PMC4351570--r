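Package: varbench
Title: Benchmarking Toolkit for Read Mappers and Variant Callers with Simulated Truth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates mutated diploid genomes and paired-end short reads with
    the true origin of every read encoded in its name, then scores external
    mapper and variant-caller output against that embedded truth. Alignment
    evaluation produces per-read correct/incorrect/unmapped verdicts, mapping
    quality ROC-like curves and quality calibration histograms. Variant
    evaluation compares a test VCF to a truth VCF inside high-confidence
    regions, excluding complex regions (an indel plus another variant within a
    short window), and reports TP/FP/FN counts, per-base true negatives,
    precision, sensitivity and specificity, variant-quality ROC curves and
    precision stratified by read depth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    VariantAnnotation,
    rtracklayer,
    SummarizedExperiment,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
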