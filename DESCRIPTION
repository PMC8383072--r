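Package: proteoscreen
Title: Screening Substrate-Degradation Gene Clusters from Label-Free
    Quantitative Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering candidate catabolic gene clusters in
    bacterial genomes from label-free quantitative proteomics. Implements
    differential-abundance calling with unique-protein handling (2-fold
    and p < 0.05 thresholds, Welch t-test on log2 intensities), sliding
    genome-window cluster detection (3 DAPs in 10 consecutive genes or 5
    in 15), average fold-change level (AFCL) scoring and ranking of
    candidate clusters, hypergeometric term over-representation analysis,
    2^-ddCt relative expression for qPCR confirmation, run-level quality
    control (Pearson correlation, detection Venn counts), and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
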