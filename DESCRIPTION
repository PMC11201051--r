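Package: maxniche
Title: Maximum-Entropy Niche Modelling and Habitat Range-Change Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end ecological niche modelling toolkit: spatial
    thinning of occurrence records, two-stage environmental-variable
    screening (zero-contribution elimination followed by pairwise
    correlation filtering), a from-scratch L1-regularised maximum-entropy
    (Gibbs) suitability model over background cells with feature expansion,
    percent contribution, permutation importance, jackknife gains and
    single-factor response curves, replicate train/test evaluation by
    presence-background AUC, habitat-suitability classification with
    spherical area accounting, binary range expansion/contraction algebra,
    and centroid-migration geometry on lat/lon rasters in ESRI ASCII grid
    format.  Includes a seeded synthetic-landscape and virtual-species
    generator so every pipeline stage can be exercised against known
    ground truth.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    geosphere,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
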