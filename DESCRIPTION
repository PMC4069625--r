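Package: possel
Title: Post-Processing and Gene-Set Enrichment for Genome-Wide
    Positive-Selection Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical inference layer for genome-wide branch-site scans
    of positive selection in protein-coding genes. Reconciles replicated
    codon-model likelihood optimisations, filters tests with convergence
    problems, maps likelihood ratios to chi-square p-values with
    Benjamini-Hochberg false-discovery control, aggregates per-branch test
    scores into lineage-level gene-family scores, and tests gene sets for
    enrichment in positively selected genes with a SUMSTAT statistic under
    a central-limit normal null, 'elim'-style decorrelation across the
    ontology graph, and permutation-based empirical false-discovery rates.
    Includes Fisher's-exact composition tests, targeted permutation tests
    for externally defined gene sets, phylogenetic utilities (canonical
    branch mapping for gene trees with missing taxa, bootstrap-guided tree
    partitioning, per-branch GC3 shifts), and a synthetic-data generator
    that emulates replicated branch-site test output with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
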