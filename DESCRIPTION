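Package: sdselect
Title: Similarity Downselection of Maximally Dissimilar Subsets
Version: 1.0.0
Authors@R:
    person("Paper", "Toolsmith", email = "toolsmith@example.org",
           role = c("aut", "cre"))
Description: Greedy similarity downselection for finding the n mutually most
    dissimilar items in a population of N given a pairwise dissimilarity
    matrix, together with best-of-k Monte Carlo sampling and exhaustive exact
    search baselines in both maximize (most dissimilar) and minimize (most
    similar) modes. Includes a conformer front-end that reads multi-record XYZ
    and SDF V2000 files, computes pairwise RMSD between corresponding atoms
    (optionally after Kabsch superposition), and builds dissimilarity matrices;
    seeded synthetic generators (Euclidean point clouds, random symmetric
    matrices, Gaussian-perturbed conformer ensembles); text and binary matrix
    persistence; and a benchmark harness comparing the three selectors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
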