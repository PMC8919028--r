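Package: commstate
Title: Community-State Dynamics and Assembly Processes in Longitudinal
    Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the assembly of low-diversity
    microbial communities sampled longitudinally across body sites.
    Discovers discrete community states from Bray-Curtis profiles
    (k-means or PAM with silhouette and Calinski-Harabasz model
    selection), fits per-site Markov transition models with stationary
    frequencies and recurrent/transient classification, estimates
    cross-site conditional detection probabilities for amplicon sequence
    variants, partitions ecological assembly processes with betaNTI and
    Raup-Crick (Bray-Curtis) null models, and builds permutation-null
    Spearman co-occurrence networks. Includes contaminant filtering,
    rarefaction, restricted-permutation PERMANOVA and ordination fitting,
    and a fully seeded synthetic cohort generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
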