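Package: tilingRT
Title: Transcription Termination Read-Through and Genomic Context Analysis
    from Strand-Specific Tiling Signal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Gene-level summarization and differential-expression calling from
    strand-specific tiling signal, a 3'UTR/ORF read-through index for detecting
    transcription-termination defects, permutation tests of genomic context
    (intergenic distances of tandem and convergent gene pairs, antisense
    coverage fractions), a size-normalized RT-PCR band ratio, and inference of
    co-purification modules from AP-MS unique-peptide matrices. Includes a
    synthetic-data generator producing annotations, signal sets and peptide
    matrices with ground-truth labels for benchmarking the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
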