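Package: heterochron
Title: Classification of Developmental Gene-Expression Divergence Between
    Larval Morphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying developmental divergence in gene expression
    between two intraspecific morphs from stage-resolved RNA-seq count data.
    Implements library-size normalization (median-of-ratios), negative-binomial
    Wald tests with Benjamini-Hochberg FDR control, fuzzy c-means clustering of
    standardized stage profiles with correlation-based cluster-number selection,
    classification of genes as conserved, heteromorphic (amount), heterochronic
    (timing) or morph-specific (adaptive per-sample expression thresholds), and
    reciprocal-F1 analyses: inheritance mode, parent-of-origin effects, and
    cis/trans regulatory architecture from allele-specific expression. Ships a
    negative-binomial simulator with per-gene ground truth so every stage of the
    pipeline can be benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
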