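Package: coexPaths
Title: Combinatorial Co-Expression Path Analysis for Multi-Condition
    RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies genes from a four-condition bulk RNA-seq design
    (a shared baseline plus three treated conditions) into combinatorial
    co-expression paths: raw counts are quantile normalized across
    samples, each treated condition is tested against the baseline with
    a negative-binomial Wald test, per-gene discrete expression states
    (induced / unchanged / repressed) are combined into state triples,
    the 26 possible non-null triples are enumerated as candidate paths,
    a ligand-informative subset is selected, and each path's gene list
    is scored for gene-set over-representation with a hypergeometric
    test. Includes a seeded negative-binomial count simulator with
    planted path structure and truth tables, so the whole pipeline is
    testable without external data, plus recovery scoring against the
    simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    optparse
biocViews: RNASeq, DifferentialExpression, GeneExpression,
    GeneSetEnrichment, Normalization, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
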