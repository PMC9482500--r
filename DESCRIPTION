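Package: ibosvm
Title: Microarray Gene Selection and Classification with HSIC-Guided Bat
    Optimization and Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of two-channel microarray gene expression for
    binary (tumour versus normal) classification. Provides log-ratio
    normalization and group-mean imputation for two-channel spot tables, fuzzy
    C-means partitioning of gene profiles, Pearson-correlation coexpression and
    differential-coexpression networks, module detection by fixed-height
    dendrogram cuts refined with partitioning around medoids, gene-subset
    selection that maximizes the empirical Hilbert-Schmidt independence
    criterion with a binary bat metaheuristic, and nested cross-validated
    support-vector-machine evaluation with precision, recall, F-measure,
    specificity, accuracy and ROC summaries. A synthetic-data generator with
    planted differential genes and block-correlated modules makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
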