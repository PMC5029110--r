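Package: ngsflow
Title: Sample-Sheet Driven NGS Workflow Execution and Analysis Utilities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An environment for building and running next-generation sequencing
    analysis workflows from R. Workflows are defined by a tabular sample sheet
    (the targets file) and per-step command templates (param files); each step
    is instantiated as a control object holding one rendered command per sample
    with registered inputs and expected outputs. A restartable serial/parallel
    runner executes the commands with per-job logs and skip-if-complete
    semantics, and downstream sample sheets are derived automatically from the
    registered outputs. Companion analysis utilities cover streamed FASTQ
    preprocessing and quality summaries, alignment statistics, strand-specific
    read counting over all annotation feature types, metagene coverage around
    start and stop codons, short open reading frame prediction, n-way Venn
    intersects, differential-expression table filtering, Markdown report
    assembly, and a synthetic-data generator (genome, annotation, simulated
    reads) so everything is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    parallel,
    tools,
    utils,
    stats,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    ShortRead
Config/testthat/edition: 3
RoxygenNote: 7.3.3
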