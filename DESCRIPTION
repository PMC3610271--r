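Package: chipdomains
Title: ChIP-Seq Peak Calling, Motif Scanning and Chromatin Domain Boundary
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps transcription-factor binding from single-base ChIP-seq tag
    data and relates it to chromatin domain organisation. Provides a
    sliding-window peak caller with vicinity suppression, position weight
    matrix genome scanning and EM matrix training from bound sequences,
    strand cross-correlation estimation of the protected-fragment length,
    exact penalised two-state segmentation of histone-modification tracks
    into signal-rich and signal-poor domains, boundary co-localisation
    statistics with per-chromosome random genomic controls and one-sided
    binomial enrichment tests, and integration of binding with gene
    annotation and two-condition expression tables. A synthetic-data module
    generates genomes, motif sites, ChIP tags, histone tracks and expression
    tables with known ground truth so that every stage of the pipeline can
    be tested in a closed loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
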