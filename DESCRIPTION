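Package: spikeshift
Title: Spike-In-Calibrated Detection of Global Chromatin and Transcription Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipelines for detecting genome-wide (global) shifts
    in a histone modification or in transcriptional output that are invisible
    to standard per-library sequencing normalization. Implements
    exogenous-genome spike-in normalization for ChIP-seq (normalization
    factors from target/spike read ratios taken as a fraction of input),
    binned cumulative-enrichment statistics with Kolmogorov-Smirnov
    comparison, empirical-Bayes batch adjustment with PCA, a Poisson
    broad-domain caller with bedtools-style post-processing, repeat-element
    classification, ERCC-anchored cell-number-normalized (CNN) RNA-seq
    expression with moderated-t differential expression, litter-matched
    negative-binomial DE overlap, and Fisher-exact gene-set enrichment.
    A synthetic-data generator with known ground truth (global scale factors,
    implanted domains, differential genes) makes every stage testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    sva,
    cluster
Config/testthat/edition: 3
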