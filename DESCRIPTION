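Package: loxstamp
Title: Simulation and Calling of Cre-loxP Timestamp Barcodes for
    Single-Cell Lineage Tracing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for inducible Cre-loxP "timestamp" barcoding of single
    cells read out by long-read sequencing. Models recombination of a
    tandem-loxP cassette carrying a static unique clonal identifier (UCI),
    enumerates the reachable barcode space, simulates ground-truthed
    nanopore-like single-cell experiments, recovers per-cell (Polylox, UCI)
    timestamp barcodes from noisy long reads with read-count and outlier
    filters, excludes low-complexity high-frequency clones under an
    independence estimator, and computes lineage-linkage statistics
    (shared-barcode edges, Spearman lineage coupling, permutation-based
    observed-to-expected enrichment).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
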