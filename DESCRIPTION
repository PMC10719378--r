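Package: cubedock
Title: Symmetric Docking of Cubic Protein Assemblies by Differential Evolution
Version: 0.1.0
Authors@R:
    person("cubedock", "developers", email = "cubedock@example.org",
           role = c("aut", "cre"))
Description: Assembles homomeric protein complexes with tetrahedral,
    octahedral or icosahedral point-group symmetry from ensembles of
    predicted subunit structures. A memetic optimizer combines
    differential evolution over six rigid-body degrees of freedom with
    symmetry-aware sliding moves and Metropolis local search, scored by
    a fast backbone point-cloud contact function (CloudContactScore)
    and a surrogate all-atom-style interface energy. Includes ensemble
    preparation from predictor outputs (confidence filtering, terminal
    trimming, redundancy pruning), symmetry analysis of native
    assemblies, a model-selection funnel (harvest, k-means clustering,
    surrogate refinement), and symmetry-aware quality metrics
    (symmetric RMSD, pairwise DockQ, assembly TM-score). All
    functionality is exercisable end to end on synthetic toy subunits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
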