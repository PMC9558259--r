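---
title: "Root-anchored completion of top-view rosette point clouds: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Root-anchored completion of top-view rosette point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosettecomplete)
```

## The problem

A single downward-looking depth camera over a rosette plant (lettuce is the
motivating crop) sees the canopy top but not the leaf bases: outer leaves
and the emerging crown foliage shade the region around the root, so the
scanned cloud has a hole where every leaf attaches. Traits computed from
such a cloud are biased — most severely the total leaf area, since the
triangulated surface simply stops at the visible inner edge of each leaf.

`rosettecomplete` repairs this geometrically, exploiting two facts about
the rosette growth habit:

1. **Leaves radiate from a central root crown.** The crown's horizontal
   position can be estimated as the centroid of the plant cloud seen from
   above, and its height as the mean height of the (flat) soil. Every
   leaf's missing base then lies between its visible root-facing edge and
   this root point.
2. **Leaves are bilaterally symmetric about their midrib.** A leaf occluded
   on one side can be repaired by mirroring the intact side across the
   vertical plane through the root and the leaf tip.

## The completion procedure

For a segmented plant cloud (color-based region growing against the soil,
arbitrated by the sign of mean excess green, ExG = 2G − R − B):

1. **Root point.** `estimate_root()`: x, y from the plant centroid, z from
   the mean soil height.
2. **Single leaves.** `segment_leaves()` re-runs color-based region growing
   with tightened spatial and color thresholds; each cluster becomes a
   `leaf_cloud` with its tip (farthest point from the root) and centroid.
3. **Outer-leaf selection.** Only leaves whose centroid sits at least a
   fraction (default 0.5) of the maximum centroid-to-root distance are
   completed. Inner leaves are barely occluded; completing them would
   inflate the area.
4. **Symmetry test.** Points are classed left/right of the root-to-tip axis
   by the sign of the 2D cross product; the imbalance ratio
   delta = 2|n_L − n_R|/(n_L + n_R) above mu = 0.23 marks the leaf
   asymmetric. The heavier side is then mirrored across the vertical
   root–tip plane and added (the original points are never moved or
   removed), and any remaining hole is filled by marching along the heavier
   side's inner rim (`find_hole_boundary()`) and sampling uniformly between
   each rim point and its mirror image.
5. **Closest edge and root fill.** The root-facing edge is the set of
   points within d_TH = d_min + var_mul × sigma of the root, where d_min is
   the smallest point-to-root distance and sigma the standard deviation of
   those distances. Edge points are screened into azimuthal bins around the
   root (one root-nearest survivor per bin) so no two retained points share
   a fill ray; `fill_uniform()` then places evenly spaced points between
   each survivor and the root.
6. **Down-sampling.** The merged cloud is radius-down-sampled to cull the
   repeated sampling completion introduces.

All completion is additive and deterministic: original points are retained
verbatim, synthetic points are flagged, and no stage consumes randomness.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `var_mul` | 1.0 | width of the closest-edge band, in units of sigma; larger admits more edge points |
| `mu` | 0.23 | symmetry threshold on delta; above it the mirror path runs |
| `n_s` | 20 | root-nearest points searched for the hole-boundary start |
| `fill_spacing` | median NN spacing | spacing of synthetic points; matches sensor density |
| `search_radius` | 3 × fill_spacing | neighbor radius of the boundary march |
| `angular_bins` | 144 | azimuthal screening bins (2.5°) |
| `completion_distance_fraction` | 0.5 | outer-leaf selection threshold |
| `final_downsample_radius` | 0.5 × fill_spacing | post-completion cull radius |
| `cell_size` | 3 mm | projected-area occupancy cell (area per cell = cell²) |
| `max_edge` | 1.5 × pitch | longest admissible mesh edge |

Three of these deserve their rationale spelled out:

* **`angular_bins` = 144.** Fill rays converge at the root; their lateral
  separation at the closest-edge radius is (edge radius) × (bin width). At
  5° bins and a 5 cm edge radius that separation (~4.4 mm) reaches the
  default meshing edge threshold, and the filled fan can no longer be
  triangulated — the repair would add points but no measurable surface.
  2.5° bins keep adjacent rays well inside `max_edge`.
* **`final_downsample_radius` = 0.5 × `fill_spacing`.** The down-sampling
  exists to remove the *repeated* sampling that mirroring and filling
  introduce. At radii near the sensor pitch it also culls genuine surface
  detail (e.g. lamina rim samples that sit closer than one pitch to the
  sampling lattice), which biases leaf area low; half the pitch removes
  near-duplicates only. The cull runs per leaf, so one leaf's points can
  never delete another leaf's repair.
* **Synthetic-point pruning.** A mirrored point that lands within one
  `fill_spacing` of an existing point duplicates surface that is already
  sampled, at a small offset — a near-coincident double layer that defeats
  the empty-ball acceptance test during meshing. Such points are dropped
  at creation; only genuinely missing regions are filled.

## Surface triangulation and trait extraction

Total leaf area uses a Gabriel-style greedy triangulation: candidate
triangles come from each point's nearest neighborhood, must have all edges
at most `max_edge` and an empty minimum enclosing ball (circumball for
acute triangles, diametral ball on the longest edge otherwise), and are
accepted greedily by increasing ball radius, rejecting any candidate that
would give an edge more than two incident triangles or cross an accepted
edge. The greedy pass is what breaks the diagonal tie on regular samplings
— both diagonals of a sampled square pass the ball test, and accepting
both would double-count the cell — and it is why planar grids reproduce
their exact area. Suspended triangles (sharing no edge, when edge-sharing
pairs exist at all) and triangles whose normal deviates more than 75° from
the local average are then dropped.

`max_edge` resolves by default to 1.5 × the cloud's *pitch* — the 90th
percentile of nearest-neighbor distances — not the median: boundary
samples and completion fills sit closer together than the sampling
lattice, drag the median down, and a `max_edge` below the lattice diagonal
collapses the mesh.

Completed plants are meshed **one leaf at a time** (the labels are carried
through completion) and the areas summed. Completion restores surface
underneath other leaves; meshing the whole cloud at once would let the
empty-ball test reject triangles wherever another leaf passes within a
ball radius of the surface being meshed. Uncompleted single-view clouds
contain no stacked surfaces and are meshed whole.

The other traits are direct: absolute height is the top of the plant above
the mean soil height, relative height the top above the fixed pot edge;
projected area is occupied-cell count × cell² on an xy occupancy grid
(half-open cells anchored at the min corner); volume and fresh weight come
from a calibrated ordinary-least-squares line on total leaf area, clamped
below at zero. Prediction from projected area is deliberately not offered
— total leaf area is the better-correlated predictor in this pipeline.

## What the synthetic generator emulates — and what it does not

`generate_rosette()` builds scenes with analytic ground truth: leaves are
sampled parametric laminae (midrib radial from an `inner_gap`, rising at
`inclination` and bending with `droop`; elliptic half-width peaking at
`width_ratio` × length; sampled at `point_spacing` with the rim itself
included so the cloud spans the full width), over a soil disc at z = 0.
Per-leaf surface areas are exact integrals of the ruled lamina, evaluated
by fine quadrature at a quarter of the point spacing.

The visible cloud models three occlusion mechanisms:

* a **root-side sector** per leaf — the innermost 15–35 % of the span
  (per-leaf uniform draw) is deleted, the shade the emerging crown foliage
  casts on every outer leaf. This is the structure the completion exists
  to repair;
* a **one-sided flank sector** on every other leaf when `asymmetry` > 0
  (the standard benchmark alternates 0 and 0.6), feeding the mirror path;
* **z-buffer visibility** at 3 mm cells with 4 mm depth tolerance, which
  removes genuinely stacked surfaces (soil under the canopy, crossing
  leaves). The tolerance must cover the depth span of a tilted lamina
  within one cell (cell × tan(lift)); a tighter tolerance would delete
  points of the very surface a ToF camera sees.

Deliberate idealizations, which bound what passing tests show about real
data:

* **Per-leaf hues are evenly spaced** on a color wheel around the green
  base, with small per-point jitter, so single-leaf segmentation is
  identifiable by construction. Real scans offer weaker, non-uniform color
  contrast between touching leaves; segmentation quality, not completion
  geometry, is then the limiting factor.
* **Same-whorl leaves are nearly co-inclined** (lift jitter 0.5°, droop
  ±5 %, crown heights within 1–2 mm). Real rosettes approximate this by
  phototropic arrangement into neighbors' gaps, but mature heads overlap
  more. Mid-leaf shading by neighbors deletes *both* flanks of a leaf
  symmetrically — damage that a method restricted to root-side filling
  and one-sided mirroring cannot recover, whatever its parameters; scenes
  dominated by it measure the sensor geometry, not the algorithm.
* **No sensor noise** beyond occlusion: no flying pixels, no multipath, no
  depth jitter. Statistical outlier removal is therefore switched off in
  the synthetic benchmark (on noiseless uniform clouds it only trims
  legitimate boundary points) while remaining the default for sensor
  configurations.
* Soil color sits at mean ExG ≈ −20 (not 0), keeping the plant/soil sign
  rule robust under per-point jitter.

## Numerical choices and degenerate inputs

* sigma in the closest-edge threshold is the sample standard deviation of
  the point-to-root distances; `sigma_mode = "printed"` switches to the
  scaled distance sum Σd/(n−1), an alternative reading of the same
  formula. With `var_mul = 0` the edge degenerates to the d_min points
  (matched with a 1e-9 tolerance).
* Points exactly on the symmetry axis count on neither side and are never
  duplicated by mirroring (their images coincide with their sources and
  are pruned).
* Post-completion symmetry is assessed about the leaf's *pre-completion*
  root–tip axis: synthetic points must not redefine the midrib the leaf
  was symmetrized on.
* Leaf tips tie-break to the lowest point index; region-growing clusters
  are maximal connected components, so seed order cannot change the
  partition.
* A leaf whose tip coincides with the root in xy has no defined axis and
  raises an error; an empty pass-through result and an empty mesh (all
  candidates rejected) are valid outputs.
* Constant-response allometric fits report R² = 1 by convention and are
  flagged degenerate.

## Problem sizes

The shipped tests and the acceptance script run the standard benchmark at
20 scenes (8–14 leaves, mean leaf length 6–15 cm, lift 15–45°, 3 mm
sampling; roughly 8,000–19,000 points per full scene), oracle comparisons
on 50 randomized clouds of 200–400 points, and analytic limits on grids up
to 10 × 10 and a 2 mm-sampled disc of radius 0.1 m. These sizes were
chosen so the whole suite exercises every operator at sensor-realistic
densities while remaining comfortable to run on a laptop.

## Known limitations

* The root estimate assumes the plant centroid lies over the crown; a
  strongly lopsided plant biases the root sideways, tilting every symmetry
  axis. The mirror repair degrades gracefully (the pruning step removes
  mirrored points that duplicate surviving surface) but does not correct
  the axis.
* The edge-to-root fill is a ruled cone; a lamina whose width profile
  bulges between the visible edge and the root is under-filled by the
  difference between the cone and the true profile. This is the main
  residual bias of completed leaf areas, and it grows with the occluded
  fraction.
* Leaves whose visible remnant is mostly gone (buried inner leaves) cannot
  be reconstructed from geometry alone; selection excludes most of them,
  and the rest contribute a small underestimate.
* One plant per scene: multi-plant clumps would need instance segmentation
  before this pipeline applies.
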