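Package: coldroots
Title: Transcriptome and Phenotype Analysis of Cold-Induced Adventitious Rooting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-course RNA-seq experiments on
    cold-induced adventitious root formation in perennial plants.
    Implements negative-binomial differential-expression calling with a
    fold-change plus adjusted-p filter, a hormone-responsive gene-set
    enrichment index with a Monte Carlo permutation test of the DEG/set
    overlap, co-expression gene selection and average-linkage clustering
    with Cluster 3.0 compatible CDT/GTR output, per-internode adventitious
    root phenotype scoring, and a seeded synthetic-data generator that
    emulates the vernalization time-course design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
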