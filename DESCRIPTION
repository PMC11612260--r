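Package: coocnull
Title: Null Model Analysis of Species Co-Occurrence with Mechanism Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and explaining non-random species co-occurrence
    in stratified presence-absence community matrices. Computes the Stone-Roberts
    C-score and per-pair checkerboard units, tests them against fixed-fixed null
    distributions generated by sequential-swap randomization (standardized effect
    sizes, two-tailed randomization probabilities, segregation/aggregation
    classification), and applies a decision-tree framework that separates
    competitive exclusion from pollution-tolerance and microhabitat-affinity
    explanations using tolerance-score gaps and PERMANOVA on principal components
    of site environmental data. Includes stratified matrix construction from
    long-format occurrence tables, SES distribution analysis across biological
    groupings, and seeded synthetic-data generators with planted structure for
    calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
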