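Package: soilspill
Title: Direct and Spillover Effects of a Soil pH Gradient on Prokaryotic Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates direct and indirect ("spillover") effects of a liming-induced
    soil pH gradient on prokaryotic community structure. Implements a predictor-group
    design with residualization against pH and PCA reduction, a hierarchical joint
    species distribution model (HMSC-style Gibbs sampler) with phylogenetic signal and
    latent residual associations, cross-validated predictive evaluation (Tjur R2 and
    correlation), per-OTU random-forest modelling with permutation-based predictor
    selection, and the supporting community and soil computations (rarefaction,
    unweighted UniFrac, PCoA, envfit, Simpson diversity, cation exchange capacity,
    static-chamber gas fluxes, thresholded correlation screen). A synthetic-data
    module emulates the field design so every stage has a ground-truth recovery test.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    vegan,
    picante,
    ranger
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
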