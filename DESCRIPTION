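Package: gliamorph
Title: Three-Dimensional Microglial Morphometry and Subpopulation Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies microglial morphology from single-channel confocal
    z-stacks. Stacks are binarized with an Otsu threshold and a minimum
    object-size noise filter, candidate cells are gated by a user-calibrated
    size range and a border-completeness criterion, and each retained cell is
    reduced to a one-voxel-wide medial skeleton by topology-preserving 3D
    thinning. Per cell the package reports cell volume, convex-hull territory,
    ramification index, branchpoint and endpoint counts, average/minimum/
    maximum branch length, distance-transform soma volume, and a 3D Sholl
    profile. A downstream clustering workflow (pooled Z-score, PCA, UMAP,
    K-means) identifies morphological subpopulations and compares their
    frequencies between treatment groups with a chi-square test, with
    normality-gated per-cluster statistics. A synthetic phantom generator
    renders soma-plus-branching-tube cells with exact ground-truth topology so
    every stage is verifiable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    yaml,
    jsonlite,
    igraph,
    uwot,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
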