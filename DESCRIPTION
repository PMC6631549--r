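Package: plsga
Title: Gene Signature Selection for Embryo Survival by PLS Regression and
    Genetic Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify small gene-expression signatures that predict
    embryonic survival rate from egg (clutch) transcriptomes.  Implements
    single-channel microarray-style preprocessing (log2 transform, per-array
    median centering, above-background presence filtering), per-gene
    differential expression between contrasted egg-quality groups with
    Benjamini-Hochberg correction, correlation-based gene prefiltering with
    redundancy pruning, PLS1 regression scored by two-fold cross-validated
    squared Pearson correlation, a genetic-algorithm wrapper search over gene
    subsets, and a permutation-based null model that calibrates gene
    selection frequencies and predictive performance.  A synthetic-data
    generator with planted predictive genes makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
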