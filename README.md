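# gliamorph

Three-dimensional morphometry of microglia from confocal z-stacks, with
morphological subpopulation clustering.

Microglia shift between ramified morphologies (long, branched processes)
and compact amoeboid forms in response to injury, stress and
pharmacological challenge. `gliamorph` quantifies that shift from
single-channel IBA-1 image stacks:

1. **Segmentation** — per-stack Otsu threshold (foreground strictly above
   the threshold, lowest tied level), 26-connected component labeling, a
   minimum-object-size noise filter, a user-calibrated size gate (largest
   single cell / smallest complete cell) that excludes merged objects and
   debris, and a border-completeness criterion (cells with less than 80%
   of their voxels away from the stack faces are excluded), with a full
   audit trail and manual overrides.
2. **Morphometry** — each cell is thinned to a one-voxel-wide skeleton by
   topology-preserving 3D thinning; the package reports, per cell:
   cell volume *V* (µm³), convex-hull territory *T* (µm³), ramification
   index *RI = T / V*, branchpoint count (junctions of the skeleton tree),
   endpoint count, average/minimum/maximum branch length (µm),
   distance-transform soma volume, and a 3D Sholl profile (skeleton-sphere
   crossings at radii *r = s, 2s, …* about the soma).
3. **Clustering** — pooled Z-score *z = (x − µ)/σ* over all cells, PCA of
   the standardized parameters, 2D UMAP embedding, K-means (default
   *k* = 3, labels ordered from amoeboid-like to ramified-like by mean
   PC1), a Pearson chi-square comparing cluster frequencies between
   treatment groups, and normality-gated per-cluster statistics
   (D'Agostino–Pearson gate; ANOVA + Bonferroni when normal,
   Kruskal–Wallis + Dunn otherwise).
4. **Reports** — two-group Mann–Whitney (exact for small samples) with
   effect size r = Z/√N and Hodges–Lehmann 95% CI, Kolmogorov–Smirnov
   distribution tests, and a JSON/markdown run report with exclusion
   counts, per-group medians and quartiles, and a full config echo.
5. **Synthetic phantoms** — soma-plus-branching-tube cells rendered as
   capsules with exact ground-truth topology (branchpoints, endpoints,
   branch lengths, analytic volumes), plus tabular feature mixtures with
   hidden archetype labels, so every stage is verifiable without any
   imaging data.

## Worked example

Generate a phantom field with three known cells, run the full measurement
chain, and compare against ground truth:

```r
library(gliamorph)

specs <- list(phantom_spec("amoeboid", seed = 1),
              phantom_spec("intermediate", seed = 2),
              phantom_spec("ramified", seed = 3))
ph <- generate_phantom_stack(specs, placement_seed = 7)
seg <- segment_stack(ph$grid)
seg$threshold
#> [1] 10
out <- measure_cells(seg$cells, default_config())
out$records[, c("cell_id", "cell_volume_um3", "territory_um3",
                "ramification_index", "branchpoints", "endpoints")]
#>   cell_id cell_volume_um3 territory_um3 ramification_index branchpoints endpoints
#> 1       1         220.250      510.0417           2.315740            1         3
#> 2       2         243.375     1379.8333           5.669577            1         3
#> 3       3         255.625   15101.0625          59.075061            5         8
sapply(ph$truth, function(t) c(bp = t$branchpoints, ep = t$endpoints))
#>    [,1] [,2] [,3]
#> bp    1    1    5
#> ep    3    3    8
```

The three cells span the amoeboid-to-ramified spectrum: at nearly equal
cell volume, the convex-hull territory grows from ~510 to ~15,000 µm³ and
the ramification index from ~2.3 to ~59, and the measured branchpoint and
endpoint counts equal the generator's ground truth exactly. On a real stack, replace the phantom with
`read_stack("stack.tif", spacing = c(0.5, 0.172, 0.172))` (z step and
pixel pitch in µm, supplied from the acquisition protocol) and calibrate
the size gate with `calibrate_size_gate()` after inspecting
`object_size_table()`.

Clustering a feature table (here synthetic, with known archetypes):

```r
tab <- generate_feature_table(c(80, 80, 80), seed = 1)
res <- cluster_pipeline(tab, default_config())
round(res$pca$variance_explained[1:2], 2)
#> [1] 69.22 11.07
table(res$labels, tab$archetype)
#>     amoeboid intermediate ramified
#>   1       80            0        0
#>   2        0           80        0
#>   3        0            0       80
res$frequency$p   # chi-square on group x cluster frequencies
#> [1] 1
```

The first two components carry ~80% of the variance, the three clusters
recover the archetypes exactly, and — since this table splits each
archetype evenly between groups by construction — the frequency
chi-square is exactly null. Use
`generate_group_mixture()` to simulate a treatment that redistributes
cells across subpopulations without changing parameter values.

A thin command-line front end is installed under
`system.file("cli", "gliamorph", package = "gliamorph")` with
`segment`, `morph`, `cluster`, `simulate` and `report` subcommands.

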