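Package: gutmaturity
Title: Microbiota Maturation Modelling, Reporter-Score Pathway Enrichment
    and Co-Occurrence Networks for Longitudinal Gut Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the age-dependent maturation of a host's
    gut microbiota from longitudinal feature tables. Trains a random-forest
    microbiota-age model on a reference (additive-free) group, fits per-group
    smoothing-spline maturity curves, detects the maturity plateau and derives
    an intestinal microbiota maturation index (IMMI) in days. Also implements
    reporter-score pathway enrichment from per-KO Kruskal-Wallis tests,
    Spearman co-occurrence networks with density and degree-centralization
    metrics, standard alpha/beta community statistics (PERMANOVA, ANOSIM),
    and a seeded synthetic-cohort generator that provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    igraph,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
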