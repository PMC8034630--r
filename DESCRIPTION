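Package: spacerhost
Title: CRISPR Spacer-Based Host Prediction for Bacteriophages
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts the bacterial host genus of a phage genome from CRISPR
    spacer evidence. Parses CRISPR-array annotations (GFF with 'binding_site'
    spacer features) into a queryable spacer store joined to a bacterial
    taxonomy, finds ungapped spacer-protospacer matches on phage genomes with
    at most k mismatches (built-in scanner or ingestion of 12-column tabular
    alignment output), and applies a four-filter decision cascade: minimum
    corrected mismatch count, number of distinct targeted genome regions,
    proximity of the matching spacer to the 5' (leader) end of its array, and
    finally the lowest common ancestor of the remaining candidate genera.
    Includes benchmark evaluation (recall and precision at taxonomic ranks via
    LCA rank agreement), a random-host null model, cutoff and filter-order
    sweeps, and a seed-deterministic synthetic data generator that plants
    protospacers with known ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
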