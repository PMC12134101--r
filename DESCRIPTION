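Package: avlipidomics
Title: Quantitative Lipidomics of Fibro-Calcific Aortic Valve Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for quantitative tissue lipidomics of
    human aortic valves, from internal-standard-spiked peak areas to
    pmol-per-mg concentrations and downstream disease-stage analytics.
    Implements lipid shorthand parsing against a 28-subclass registry,
    type I/II isotopic corrections with single-point class-matched
    calibration, calibration-linearity and recovery diagnostics,
    stage/sex differential statistics (Welch t, one-way ANOVA, fold-change
    volcano tables), lipoprotein-proxy ratios (LPC/PC, Cer/SM, SM/PC,
    CE/TG, LPE/PE), Gaussian-mixture trend clustering of stage
    trajectories, structure-aware UMAP lipidome topology built on an exact
    maximum-common-edge-subgraph backbone distance, sphingolipid flow
    decomposition for Sankey diagrams, and a ground-truthed synthetic
    study generator emulating the cohort's effect structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    mclust,
    uwot,
    ChemmineR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster
Config/testthat/edition: 3
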