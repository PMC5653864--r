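Package: morphorates
Title: Rates, Disparity and Diversity Dynamics of Discrete Morphological
    Evolution on Time-Calibrated Fossil Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the tempo and mode of morphological
    diversification in fossil clades from discrete character matrices and
    samples of time-calibrated trees.  Implements maximum-likelihood
    ancestral state reconstruction under the Mk model, per-branch rates of
    character change normalised by time and character comparability,
    Poisson likelihood-ratio tests for per-time-bin rate heterogeneity with
    Benjamini-Hochberg correction and aggregation across a posterior-like
    sample of trees, Gower-distance disparity with bootstrap confidence
    intervals, principal-coordinates morphospace and phylomorphospace
    ancestral scores, range-through taxonomic diversity, and standardized
    diversity-disparity trajectories.  A fossil birth-death simulator with
    epoch-heterogeneous character evolution and a complete truth ledger
    makes every stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    Rcpp,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
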