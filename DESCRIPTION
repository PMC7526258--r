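Package: schictrans
Title: Statistically Frequent Interchromosomal Interactions in Single-Cell Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genome regions whose interchromosomal (trans)
    chromatin contacts recur across single cells profiled by single-cell
    Hi-C. Chromosomes are partitioned into equal-sized bins (optionally
    shifted by a sliding-window offset), an unweighted cross-chromosome
    contact network is built per cell, and the recurrence of each edge
    across cells is scored with a binomial upper-tail test whose success
    probability pools the per-cell edge densities (max, mean or min of
    n_i/M over the node-filtered edge search space). Bonferroni-adjusted
    p-values select significant edges and the regions they touch. Also
    provides region-set comparison (exact and both-ends-overlap across
    sliding windows), randomization-based genomic-feature enrichment
    z-scores, BED/Circos-link/TSV output, and a synthetic single-cell
    contact simulator with planted frequent edges for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    callr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
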