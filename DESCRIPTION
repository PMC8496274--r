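Package: poreMethyl
Title: Downstream Analysis of Nanopore CpG Methylation Calls
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns per-read log-likelihood-ratio methylation calls from
    nanopore signal-level callers into per-site methylation frequencies,
    validates them against CpG observed/expected depletion of a reference
    transcriptome, and performs a two-group genome-wide differential
    methylation analysis: per-position Welch t-tests with Benjamini-Hochberg
    false discovery rate control, detection of zero-variance "perfect"
    differences, and merging of flagged positions into differentially
    methylated regions. A synthetic-data module generates CpG-depleted
    sequences, per-read call tables with a bimodal log-likelihood-ratio
    mixture, and multi-sample group designs with injected differentially
    methylated regions, so every stage of the pipeline can be exercised
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Sequencing, DifferentialMethylation
RoxygenNote: 7.3.3
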