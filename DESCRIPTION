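Package: taxvote
Title: Weighted-Voting Consensus of Per-Read Taxonomic Classifications
Version: 0.1.0
Authors@R:
    person("taxvote", "maintainers", email = "taxvote@example.org",
           role = c("aut", "cre"))
Description: Integrates per-read outputs of multiple metagenomic taxonomic
    classifiers (Kraken2, Centrifuge, Kaiju, CLARK and generic two-column
    dialects) into a single consensus by weighted voting, in a high-recall
    ("merge") and a high-precision ("merge_p") variant. Provides an NCBI
    taxonomy dump parser with lineage, rank-projection and lowest-common-
    ancestor queries; a rank-resolved evaluation scheme (confusion counts
    and accuracy/precision/recall plus a modified false-positive rate
    defined as FP over all reads, suited to simulated data without true
    negatives); and a seeded simulator of toy taxonomies, ground truth and
    heterogeneous classifier error profiles so the whole pipeline is
    testable offline. Includes a command-line driver for reproducible
    simulate/merge/evaluate runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
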