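Package: regenphase
Title: Temporal Phase Analysis of Regeneration Time-Course Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bulk RNA-seq time courses of regenerating
    axolotl structures (mandible and limb). Provides counts-per-million
    normalisation, expression filtering for low-replicate time-course designs,
    z-score standardisation of temporal profiles, gap-statistic selection of
    the number of k-means clusters, Pearson cluster-score gene selection,
    rule-based assignment of clusters to temporal phase groups, cross-structure
    shared-gene overlap statistics, defect morphometry arithmetic, and a
    negative-binomial count simulator with planted temporal archetypes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
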