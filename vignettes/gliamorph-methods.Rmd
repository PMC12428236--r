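---
title: "Quantifying microglial morphology in 3D: methods and design notes"
author: "gliamorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial morphology in 3D: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliamorph)
```

# The problem

Microglia — the resident immune cells of the central nervous system — shift
between highly ramified morphologies (many long, branched processes,
classically read as surveillant) and compact amoeboid forms (few short
processes, classically read as reactive). Quantifying that shift from
IBA-1-stained confocal z-stacks requires segmenting individual cells in 3D,
reducing each cell to a measurable skeleton, and summarizing cells with a
small set of morphological parameters. Because microglial populations are
heterogeneous, single-parameter group means hide structure; an unsupervised
clustering of the per-cell parameter vectors can instead reveal
subpopulations and treatment-induced shifts in their relative frequencies.

`gliamorph` implements this pipeline end to end: Otsu thresholding and
noise filtering, user-calibrated size gating and a border-completeness
criterion, topology-preserving 3D skeletonization, eight morphological
parameters plus soma volume and a 3D Sholl profile per cell, and a
clustering workflow (pooled Z-score, PCA, UMAP, K-means, frequency
chi-square, normality-gated per-cluster statistics). A synthetic phantom
generator provides ground-truth-known inputs for every stage.

# Segmentation

**Thresholding.** The Otsu threshold is computed per stack over the native
integer histogram: the level `t` maximizing the between-class variance of
the background/foreground split, foreground strictly above `t`, lowest level
on ties. Computing it per stack (never pooled across a cohort) follows how
such tools are used in practice; the strict inequality and tie rule make
binarization bit-exact.

Intensity-histogram thresholding has a documented failure mode for very
sparse images: when foreground occupies a fraction of a percent of the
volume, the between-class variance of a split *inside* the broad background
mode can exceed that of the true background/foreground split, and the
threshold collapses into the background. The phantom generator's defaults
(tight fields of view, a low background offset of 10 of 255 with
shot-noise-scaled variance) keep synthetic stacks on the safe side of this
trade-off; on real data, high background staining can push stacks over it,
which is a property of the thresholding method, not of any implementation.

**Object selection.** Connected components are labeled under 26-connectivity
by default, so thin diagonal processes do not fragment; components below the
user's minimum object size are removed (the noise filter). The size gate is
calibrated from two user-identified reference objects — the largest single
(non-merged) cell and the smallest complete cell; anything larger is
presumed a merged multi-cell object, anything smaller debris. In this
package the interactive step is replaced by explicit cell ids (or voxel
counts) so batch runs are reproducible; `object_size_table()` prints the
ranked sizes the interactive step would show. Completeness is
operationalized as the fraction of a cell's voxels away from the six faces
of the stack: below 0.8 the cell is flagged incomplete. The conventional
field criterion — at least 80% of the soma and its projections inside the
imaged volume — is not voxel-precise; weighting every voxel equally is the
simplest faithful reading. Manual per-cell overrides win over both filters, and every object
keeps its audit trail (`included`, `exclusion_reason`).

# Skeletonization

Each included cell is thinned to a one-voxel-wide curve skeleton by
sequential removal of *simple points* — voxels whose deletion provably
preserves local topology (one 26-connected foreground component among the
26 neighbors, one 6-connected background component in the 18-neighborhood
touching a face). Removal is organized as six directional subiterations per
cycle with the candidate set frozen per pass and ordered by the Euclidean
distance transform, so objects peel layer by layer, the skeleton stays
medially centered, and erosion along a process is bounded to about one
voxel per cycle. Curve endpoints — voxels with a single foreground
neighbor, or two mutually adjacent ones (digital line ends can carry a
chord adjacency) — are never removed. This combination was validated
against generator ground truth: simpler orderings (a single global priority
queue, or one frozen layer per iteration) can consume an entire short
branch end to end before its tip locks, silently deleting real processes.

Thinning runs on the voxel lattice with the anisotropic spacing entering
through the distance transform and all physical lengths; resampling to
isotropic voxels beforehand would change topology unpredictably.

**Graph reduction.** Skeleton voxels are connected under 26-adjacency with
physical step lengths as weights. Digital curves carry *chord* adjacencies
(a diagonal shortcut across two axis steps) that would masquerade as
junctions, so the voxel graph is reduced to its minimum spanning tree; the
number of independent cycles removed is recorded (`n_cycles`), and
microglial processes are biologically tree-like, so genuine cycles are not
expected.

**Junctions, endpoints, pruning.** Branchpoints are 26-connected clusters
of degree-≥3 skeleton voxels (a thick junction counts once); endpoints are
degree-1 voxels. Because several processes meet in the soma, junction
clusters with voxels inside the cell's *maximal inscribed sphere* (center =
distance-transform argmax, radius = its value) are merged into a single
soma hub, and leaf branches lying entirely inside that sphere are removed
as thinning residue — a genuine process leaves the cell body. Terminal
branches shorter than `prune_length` (default 2 µm) are pruned iteratively
as surface artifacts. A skeleton of at most one voxel, or lying wholly
inside the inscribed sphere, is flagged `degenerate_skeleton` and reports
zero counts and lengths — zeros are emitted only together with that flag,
so they can be filtered deliberately rather than silently contaminating
statistics.

**Branch lengths.** A branch is the path between consecutive critical
nodes. Its length is the sum of physical step lengths along the path after
resampling it every six voxels (~3 µm at the default spacing; a voxel
stride keeps lengths exactly proportional to spacing). The resampling
matters: thinning leaves a ±1-voxel wobble around the true medial axis,
and summing raw voxel-to-voxel steps inflates oblique branch lengths by up
to ~30%; coarse chords suppress the wobble while losing under 1% to
genuine curvature at microglial process tortuosity. On straight-tube
phantoms the measured length is within a voxel pitch of truth.

# The eight parameters, soma, and Sholl

* **Cell volume** — voxel count × voxel volume.
* **Territory** — volume of the 3D convex hull of the cell's voxel centers
  (computed from boundary voxels only; an incremental hull in C++). Using
  voxel centers rather than corners shrinks the hull by about half a voxel
  symmetrically across groups; for a compact convex cell that raw hull is
  genuinely smaller than the voxel volume, so the reported territory is
  clamped from below at the cell volume (the raw hull is returned
  alongside) and the ramification index is exactly 1 rather than silently
  below it. Collinear/coplanar cells are flagged degenerate.
* **Ramification index** — territory / volume; ≥ 1 by construction, near 1
  for compact amoeboid cells, large for ramified cells.
* **Branchpoints, endpoints, average/min/max branch length** — from the
  skeleton as above.
* **Soma** — center at the distance-transform argmax (ties broken by lowest
  (z, y, x)); soma volume = cell voxels with distance value ≥
  `soma_fraction` (default 0.5) of the maximum, restricted to the connected
  component containing the center.
* **Sholl profile** — for spheres of radius `step, 2·step, …` about the
  soma center, the number of skeleton edges straddling each sphere
  (min distance < r ≤ max distance), i.e. skeleton-sphere crossings, the
  standard 3D definition.

Interior cavities in a cell mask (intensity dropouts under noise) are
filled before the distance transform and thinning; they would otherwise
displace the soma and force the skeleton around phantom holes. Cell volume
is still reported from the raw fluorescent voxels.

# Synthetic phantoms

The generator renders each cell as a soma ball plus a random tree of
capsule (cylinder + hemispherical cap) segments, so analytic volumes exist.
Growth: from each active tip the direction is perturbed by a tortuosity
angle per segment; tips bifurcate with probability `bifurcation_prob`
until `max_branch_depth`. Primary processes run from the soma center to
`soma_radius + L`, so every recorded process protrudes `L` beyond the soma.
Three archetype presets emulate the microglial spectrum (soma radius
3–3.5 µm, process radius 0.6–0.8 µm, segments ~5.5–12 µm, 3/3/4 primaries
and depth 1/2/3 for amoeboid/intermediate/ramified), rendered at 0.5 µm
isotropic voxels — the axial step used in the imaging protocol the package
targets; isotropic sampling keeps digital topology clean at desk scale.

Phantom design constraints guarantee a well-posed ground truth:

* segments are truncated below 5.5 µm — a measured branch is shorter than
  the true branch by tip erosion (~2–3 voxels), the cap radius and the
  junction-cluster offset (~3.5 µm in total), and anything measuring below
  the 2 µm prune threshold is removed, so shorter true branches would sit
  below the measurement's resolvability limit by construction;
* daughter branches of a bifurcation keep ≥ 45° between them, and every
  segment keeps an exact minimum clearance (one tube diameter plus 1 µm,
  exact segment–segment distance) from all non-adjacent segments — a
  candidate violating it terminates its branch, and the recorded topology
  always describes the realized, collision-free tree;
* noise is Gaussian with SD proportional to √intensity (the usual
  approximation to photon shot noise), `noise_sd` giving the SD at the
  foreground plateau so that SNR = (foreground − background)/`noise_sd`;
* cells never overlap (rejection-sampled placement, or a tight per-cell
  field of view when the grid auto-sizes).

What the phantoms do **not** emulate: optical PSF blur (available as an
optional Gaussian-blur flag, off by default), depth-dependent attenuation,
true Poisson statistics, touching cells, and background staining texture.
Passing recovery tests therefore demonstrates the correctness of the
measurement chain on geometrically realistic cells, not robustness to every
optical artifact of real confocal data.

With these conditions the pipeline recovers branchpoint and endpoint counts
exactly on noise-free phantoms (50 per archetype in the verification suite),
within ±1 at SNR 5, and per-cell mean branch length within two voxel
pitches of truth. The per-cell *mean* is the compared statistic because a
branch-by-branch pairing between measured and true trees is not
well-defined once counts can differ.

# Clustering workflow

The order is fixed: pooled Z-score, PCA, UMAP, then K-means.

* **Z-score** uses the pooled mean and *sample* (n−1) SD over all cells —
  never per group — so both groups land on one common scale. Constant
  columns become zeros with a warning; rows with missing parameters are
  dropped with a message (degenerate-skeleton cells are the expected
  source).
* **PCA** is the eigen-decomposition of the covariance of the standardized
  matrix (= correlation matrix of the raw parameters). Variance shares are
  100·λᵢ/Σλ; each loading vector's largest-magnitude entry is made
  positive for reproducible signs. All eight components are passed on by
  default (no stated cutoff is imposed).
* **UMAP** (via `uwot`) embeds the PC scores in 2D with `n_neighbors = 15`,
  `min_dist = 0.1`, 200 epochs — ample for a few hundred cells — and a
  fixed seed, single-threaded, so embeddings are exactly reproducible. The
  embedding is deterministic per seed but only approximately equivariant
  under row permutation (stochastic gradient order); the deterministic
  stages (Z-score, PCA, K-means given a fixed space) are exactly
  permutation-equivariant.
* **K-means** runs on the 2D embedding by default (`cluster_space = "pca"`
  clusters PC scores directly as a sensitivity analysis), best of `n_init`
  restarts. `k` defaults to 3 — the number of morphological subpopulations
  the workflow is designed around — and `silhouette_scan()` supports
  choosing `k` when it is not fixed a priori. Cluster ids are relabeled by
  ascending cluster-mean PC1, so "cluster 1/2/3" orders from amoeboid-like
  to ramified-like and is stable across seeds.
* **Frequencies** between treatment groups are compared with a Pearson
  chi-square on the group × cluster table (df = (r−1)(c−1)); expected
  counts are reported and cells with expected counts under 5 flagged.
* **Per-cluster comparisons** are gated by a D'Agostino–Pearson omnibus
  normality test on the pooled parameter values (implemented from the
  standard skewness/kurtosis formulas; no installed package provides it):
  normal parameters get one-way ANOVA with Bonferroni-adjusted pooled-SD
  pairwise t tests, non-normal ones Kruskal–Wallis with Dunn's rank
  comparisons (tie-corrected z statistics, Bonferroni-adjusted). Parameters
  with a cluster under 3 cells or degenerate variance are flagged and not
  tested.

On synthetic three-archetype tables with ≥ 2 pooled-SD separation
(n = 240), the pipeline recovers the archetype partition with median
adjusted Rand index above 0.9 over 20 seeds. For the mixing-proportion
shift design (1/3,1/3,1/3 versus 0.5,0.3,0.2 at n = 120 per group) the
pipeline's detection rate over 200 seeds sits at the statistical ceiling
of the test itself: the 2×3 Pearson chi-square evaluated on the *true*
archetype labels has power ≈ 0.73 at this effect size and sample size
(noncentrality ≈ 8.2), and because clustering recovery is near-perfect the
pipeline detects at essentially the same rate — larger samples or stronger
shifts raise it accordingly. The type-I error under no shift stays at the
nominal 5% (500 replicates, evaluated on the generator's true labels; the
test's calibration does not depend on where the labels came from).

# Group reports

`compare_groups()` performs the two-group analysis per parameter:
two-sided Mann–Whitney U (exact for small samples without ties), effect
size r = Z/√N from the tie-corrected normal approximation of U (the
conventional signed rank-biserial-style definition; the choice is recorded
in the output), the Hodges–Lehmann median-difference estimate with a 95%
confidence interval, and the two-sample Kolmogorov–Smirnov test. All
statistics are at the individual-cell level, which inflates the apparent
sample size relative to animals; the output carries that caveat verbatim
plus per-animal cell counts so pseudoreplication is visible. Mixed-effects
modeling of Sholl curves is deliberately out of scope; standard packages
(`lme4`, `nlme`) handle it once per-cell profiles are exported.

# Numerical choices and degenerate inputs

* Foreground is strictly above the threshold; ties at the threshold are
  background (bit-exactness).
* Constant stacks raise a degenerate-histogram error rather than guessing.
* Hull construction treats near-coplanar inputs as degenerate
  (territory = volume, flagged).
* Distance-transform ties (soma center) break to the lowest (z, y, x).
* All seeds are explicit arguments; UMAP and K-means are single-threaded
  and reproducible bit-for-bit for a fixed seed.
* Simulation scales in the test suite: 50 phantoms per archetype
  (noise-free), 25 per archetype (SNR 5), 20 clustering seeds, 200
  detection seeds, 500 null replicates.

# Known limitations

* The size gate handles merged cells only by exclusion; there is no
  watershed splitting of touching cells.
* Very sparse fields can defeat Otsu thresholding (above); inspect
  `segment_stack()$threshold` when foreground is well under 1% of the
  stack.
* Branch lengths are digital-geodesic approximations; sub-voxel spline
  fitting is not attempted.
* The hull-of-voxel-centers territory convention shrinks territories by
  ~half a voxel relative to a surface-mesh convention; comparisons across
  groups are unaffected, absolute values differ accordingly.
* UMAP embeddings are reproducible per seed but not identical across
  uwot versions; downstream counts and statistics are robust to this, the
  2D coordinates themselves are not.
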