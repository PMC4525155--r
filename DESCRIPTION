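Package: rertools
Title: Quantitative ChIP-Seq Enrichment Profiling with qPCR-Anchored
    Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds relative enrichment ratio (rER) profiles from aligned
    ChIP-seq and input read positions on a fixed-width bin grid, with
    smoothing, input-coverage masking and genome-wide mean-1 normalization.
    Calls binding-site peaks by threshold-contiguous runs in rER or
    normalized read intensity (modified RPKM) mode with sample-swap false
    discovery rate estimation, validates and rescales profiles across
    samples against ChIP-qPCR anchor measurements, and computes gene- and
    promoter-centric statistics: TSS/TTS inference from CDS plus UTR
    lengths, metagene profiles and enrichment heat maps, peak-to-TSS
    distances, genome-fraction and CpG-island association odds ratios,
    expression stratification, and gene-set overlap tests. Includes a
    synthetic-data generator that emulates transcription-coupled protein
    occupancy (TTS-biased gene-body or TSS-spike modes), Poisson-sampled
    coverage, mappability dropouts and noisy qPCR readouts, so that every
    stage of the pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
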