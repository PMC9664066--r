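# eatcoloc

Does epicardial adipose tissue (EAT) sit preferentially against fibrotic
regions of the left-atrial (LA) wall? `eatcoloc` is an R package that
answers this spatial-colocalization question from labeled 3D image
volumes: an endocardial/wall segmentation with an LGE intensity volume on
one acquisition frame, and a fat segmentation with anatomical landmarks
on another. It is aimed at cardiac image-analysis researchers who have
segmentations in hand (or want a fully synthetic test bed) and need the
geometry and statistics between segmentation and conclusion.

## What it computes

For every vertex `v` of the triangulated LA surface, against a fat model
of volume-weighted sample points `p_k` (weights `w_k`, mm³):

- **EAT proximity**  `d_EAT(v) = min_k ‖v − p_k‖`  (mm)
- **local EAT volume**  `V_EAT(v) = Σ_{‖v−p_k‖ ≤ r} w_k`  (mm³), closed
  ball of radius `r = 5` mm

The pipeline around the metrics:

1. **Wall**: metric dilation of the endocardial mask by 2 mm (exact
   Euclidean distance transform, anisotropic voxels supported) minus the
   mask.
2. **Fibrosis**: wall voxels above `μ + k·σ` (default `k = 3`) of the
   non-enhanced wall signal, estimated by sigma-clipped median/MAD;
   burden reported as % of wall volume.
3. **Reconstruction**: closed triangle mesh of the LA by marching
   tetrahedra on a mildly smoothed occupancy field; fat voxels converted
   to volume-weighted samples at ≤ 1 mm spacing.
4. **Registration**: closed-form rigid (rotation + translation)
   landmark fit of the fat frame onto the fibrosis frame.
5. **Statistics**: per-vertex maps stratified into fibrotic vs
   non-fibrotic samples, compared by Mann-Whitney U (exact enumeration
   for small tie-free samples, tie-corrected normal approximation
   otherwise), with median (Q1, Q3) reporting, coverage fractions, and
   BSA-indexed fat volumes (Mosteller).

A synthetic phantom module generates ellipsoidal-LA cases and cohorts
with known fibrotic caps, fat depots placed `near` to / `far` from them /
at `random`, a Gaussian LGE intensity model, and a known rigid
misalignment between frames — so every stage is validated against ground
truth and analytic geometry.

## Worked example

Three synthetic cases with fat depots planted inside the fibrotic
regions (`near` mode), run end to end:

```r
library(eatcoloc)
cfg <- pipeline_config(n_cases = 3, coloc_mode = "near", seed = 7)
res <- run_pipeline(cfg)
res$summary
#> <cohort_summary> 3 cases (pooled aggregation)
#>   d_eat: <group_comparison> n = 18408 vs 76300 | medians 3.135 (1.053, 5.543) vs 16.61 (11.93, 21.81) | U = 36944861.0 | p = 2.23e-308
#>   v_eat: <group_comparison> n = 18408 vs 76300 | medians 29 (0, 112.2) vs 0 (0, 0) | U = 1183741749.0 | p = 2.23e-308
#>   coverage: fibrotic 69.5%, non-fibrotic 1.7%
```

Reading the output: of 18,408 fibrotic and 76,300 non-fibrotic surface
vertices pooled over the cohort, the median distance to fat is 3.1 mm at
fibrotic vertices versus 16.6 mm elsewhere — the planted colocalization,
recovered with an overwhelming two-sided Mann-Whitney p. The median
local fat volume within 5 mm is 29 mm³ at fibrotic vertices and zero
elsewhere, and 69.5% of fibrotic vertices have any fat within 5 mm
versus 1.7% of non-fibrotic ones. Per-case numbers are in `res$cases`:

```r
res$cases[, c("case", "fibrosis_percent", "la_eat_mL", "total_eat_mL")]
#>   case fibrosis_percent la_eat_mL total_eat_mL
#> 1    1           20.046     2.915       16.059
#> 2    2           20.039     1.883       17.175
#> 3    3           20.098     2.546       15.134
```

Generating a `far`-mode cohort instead reverses the d_EAT inequality
(fibrotic vertices farther from fat), which is the direction consistent
with no fat infiltration of fibrotic regions.

The statistical kernel is usable on its own:

```r
mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#> <group_comparison> n = 3 vs 3 | medians 2 (1.5, 2.5) vs 5 (4.5, 5.5) | U = 0.0 | p = 0.1 (exact)
```

Setting `output_dir` in `pipeline_config()` additionally writes, per
case, the surface as VTK polydata with `fibrotic`, `d_eat_mm` and
`v_eat_mm3` point data, the fat model as CSV, the fitted transform as
JSON, plus cohort-level CSVs, a JSON summary stamped with a config hash,
and a log. A thin command-line wrapper lives in
`inst/scripts/eatcoloc.R`.

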