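Package: fundisp
Title: Scale-Dependent Functional Dispersion of Ecological Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how the functional structure of ecological
    communities changes across nested spatial scales and environmental
    gradients, motivated by surveys of lake macrophyte vegetation. Builds
    trait dendrograms from mixed continuous and categorical traits (Gower
    and Euclidean distances, UPGMA clustering), computes abundance-weighted
    functional alpha diversity (mean pairwise and nearest-neighbour trait
    distance) and beta diversity (between-community pairwise and
    nearest-neighbour dissimilarity) from cophenetic distances, standardises
    them against taxa-shuffle null models into standardized effect sizes
    (SES), tests group-level departure from random assembly with Wilcoxon
    signed-rank tests, decomposes SES variance over a plot / depth / lake /
    region hierarchy with nested random effects, and estimates SES trends
    along scale-specific gradients with linear mixed models. A synthetic
    survey generator with known environmental-filtering strength provides
    ground truth for end-to-end calibration and recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    ape,
    lme4,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr,
    optparse
Config/testthat/edition: 3
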