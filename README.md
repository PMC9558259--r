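# rosettecomplete

Geometric completion of single-view (top-down) point clouds of rosette
plants, and growth-trait extraction from the completed clouds.

A downward-looking depth camera over a lettuce sees the canopy top but not
the leaf bases: the crown foliage shades the region around the root, so
every leaf's attachment zone is missing from the scan. Surface area
measured from such a cloud is severely underestimated. This package
repairs the cloud using the rosette growth habit itself — leaves radiate
from a central root crown and are bilaterally symmetric about their midrib
— and then measures the standard growth parameters.

The pipeline, for a colored cloud split into plant and soil by color-based
region growing (arbitrated by the sign of mean excess green,
ExG = 2G − R − B):

1. **Root point** `p_root = (x_c, y_c, z_soil)`: plant centroid in xy,
   mean soil height in z.
2. **Single-leaf segmentation** by region growing with tightened spatial
   and color thresholds; only outer leaves (centroid beyond half the
   maximum centroid-to-root distance) are completed.
3. **Symmetry test** about the root-to-tip axis:
   `delta = 2 |n_L − n_R| / (n_L + n_R)`; above `mu = 0.23` the heavier
   side is mirrored across the vertical root–tip plane and the remaining
   hole filled along its traced boundary.
4. **Closest-edge fill**: points within `d_TH = d_min + var_mul * sigma`
   of the root form the leaf's root-facing edge; after azimuthal
   screening, points are uniformly sampled between each edge point and the
   root.
5. **Traits**: absolute/relative height (`H_abs = H_top − H_soil`,
   `H_rel = H_top − H_pot_edge`), projected canopy area by grid occupancy
   (`S_pa = N_cells × cell²`), total leaf area by Gabriel-style greedy
   surface triangulation, and allometric volume/fresh-weight prediction
   from total leaf area.

A synthetic rosette-scene generator with analytic ground truth (and
z-buffer occlusion plus root-side crown shade) makes every stage testable
without sensor data, and an ExG imaging module computes marker-calibrated
reference areas from top-view photographs.

## Worked example

```r
library(rosettecomplete)

# a synthetic 10-leaf rosette seen from above, with crown-shade occlusion
scene <- generate_rosette(rosette_spec(n_leaves = 10, seed = 7))
scene
#> <synthetic_scene> 10 leaves, 11271 full / 6686 visible points, true total leaf area 0.0511 m^2

# split plant from soil, complete, and measure
seg  <- classify_plant_soil(
  region_grow_color(scene$visible, 0.005, 40, 50), scene$visible)
done <- complete_plant(seg$plant, seg$soil)

raw_area  <- mesh_area(triangulate(seg$plant))
comp_area <- total_leaf_area(done)
c(truth = scene$truth$total_area, raw = raw_area, completed = comp_area)
#>      truth        raw  completed
#> 0.05110321 0.03687426 0.05538898
```

The uncompleted visible cloud underestimates the true total leaf area by
about 28 %; after completion the measurement lands within 9 % of the
truth. `attr(done, "leaf_info")` reports, per leaf, the pre- and
post-completion symmetry ratio and whether the leaf was selected for
completion.

Whole batches run through `run_pipeline()` /
`pipeline_config()` (file inputs in PLY/PCD are supported), and
`run_benchmark(n_scenes, base_seed)` scores the pipeline on the standard
synthetic benchmark against the generator's analytic truths. A thin
command-line front end with `synth`, `run`, `benchmark` and `groundtruth`
subcommands is installed under `inst/cli/`.

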