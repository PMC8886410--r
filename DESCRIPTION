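Package: growthlaw
Title: Growth-Law Decomposition of Gene Expression and Proteome Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Separates growth-rate-dependent from nutrient-specific gene
    expression in steady-state cultures profiled across conditions with
    measured growth rates. Fits per-gene growth laws with repeated-median
    linear models (Siegel robust regression), derives an abundance-free
    fold-change statistic, and assigns genes to R/P/Q proteome sectors by
    tail-based false discovery rates. Includes iBAQ mass- and number-fraction
    quantification, attenuation-corrected (Spearman) protein-mRNA
    correlations, growth-rate-removed differential expression built on
    RMLM-predicted normalization factors and a synthetic reference condition,
    hierarchical clustering and PCA structure analysis, Fisher and preranked
    gene-set enrichment, and a negative-binomial/lognormal synthetic-data
    generator emulating a multi-condition turbidostat study design.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    DESeq2
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
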