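Package: ontotraj
Title: Ontogenetic Allometric Trajectory Analysis for Comparative Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the evolution of postnatal ontogenetic
    allometry across species. Converts linear measurements and 2D landmark
    configurations into size-corrected shape data (log-shape ratios,
    generalized Procrustes analysis with bending-energy semilandmark sliding
    and object symmetry), fits per-species shape~size trajectories with
    residual-randomization permutation inference (isometry test, homogeneity
    of slopes, pairwise angle/length/intercept comparisons, hierarchical
    partitioning of disparity drivers), runs a heterochrony test battery
    (peramorphosis, ontogenetic scaling, size-shape dissociation), contrasts
    juvenile and adult morphology on a phylogeny (ontogenetic
    convergence/divergence D test, multivariate Blomberg's K and delta-K,
    simulation-based phylogenetic MANOVA, phylomorphospace coordinates), fits
    eight trait-evolution models (BM, multi-rate BM, OU, multi-optimum OU,
    early burst, matching competition, linear and exponential diversity
    dependence) compared by AICc weights, and estimates branch-specific
    evolutionary rates by phylogenetic ridge regression with clade shift
    detection and robustness resampling. A synthetic-data generator produces
    trees, habitat regimes and individual ontogenetic series with the
    statistical structure every stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
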