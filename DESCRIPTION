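Package: repanner
Title: Clonotype Analysis for Antibody Phage-Display Panning Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for exploring high-throughput sequencing of antibody
    libraries across phage-display panning rounds. Reads clonotype tables in
    MiXCR-export or AIRR Rearrangement TSV dialects plus per-sequence binding
    CSVs, applies frame/count/length trimming, and computes rarefaction
    curves, Shannon and inverse Simpson diversity, pairwise sample-overlap
    matrices (relative overlap, Morisita-Horn, Jaccard, Sorensen-Dice), CDR
    length distributions, positional amino-acid composition for logo plots,
    Levenshtein-distance clustering (dendrograms and cutoff graphs), sequence
    graph transform embeddings projected to two dimensions with PCA and
    t-SNE, and binding-data overlays that nominate untested sequences near
    high-affinity binders. A panning-campaign simulator with ground-truth
    selection coefficients supports validation, and a command-line front-end
    drives the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
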