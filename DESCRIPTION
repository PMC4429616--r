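Package: dcgscan
Title: Differential Methylation-Expression Correlation Analysis in Tumor-Normal Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially correlated genes (DCGs): genes whose
    DNA methylation-gene expression correlation differs between tumor and
    normal samples, independently of level differences. Provides beta/M
    conversion and quantile normalization, per-gene and per-CpG correlation
    engines, genome-wide paired Wilcoxon comparisons with subsampling for
    unequal group sizes, Fisher z-tests for correlation differences with
    Stouffer gene-level combination and Mantel autocorrelation diagnostics,
    penalized-spline regression of correlation on TSS distance, descriptive
    summaries, Monte-Carlo genomic-interval preferential-overlap tests and
    hypergeometric gene-set enrichment against a custom background, plus a
    seeded synthetic-data generator with known correlation structure for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
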