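# dirprop — deformable registration and contour propagation for adaptive radiotherapy

Lung tumours shrink, grow and shift during a course of radiotherapy. Adaptive
replanning needs the target and organ-at-risk contours redrawn on every
repeat CT, which is one of the most time-consuming steps of the workflow.
`dirprop` automates it: it estimates a deformable mapping between the
pre-treatment and a mid-treatment CT, carries the pre-treatment regions of
interest (ROIs) through that mapping, and quantifies how well the propagated
contours agree with reference (physician-drawn) ones. It is aimed at medical
physicists and imaging researchers who want an open, scriptable, fully
testable implementation of this pipeline with a synthetic ground-truth
phantom for validation.

## What is inside

Three deformable registrars, each driven by a different image property,
all emitting a displacement vector field `u` on the fixed (mid-treatment)
grid in the pull-back convention — the vector at fixed voxel `x` points to
the corresponding pre-treatment location `x + u(x)`:

* **Fast-symmetric Demons** (intensity/optical flow). Per-voxel update

  `u = 2 (f − m) (∇f + ∇m) / (‖∇f + ∇m‖² + α² (f − m)²)`, `α = 1 / mean spacing`,

  iterated over a 8×/4×/2×/1× multi-resolution pyramid with at most
  200/100/100/30 iterations, Gaussian field smoothing of 3/3/0.9/0.7 mm per
  level and 64-level / 7-point histogram matching.
* **Morphons** (local phase). Six frequency-domain log-normal quadrature
  filters along icosahedral directions; the local phase difference
  `Δφ_k = arg(q_fixed · conj(q_warped))` constrains the displacement through
  the filter's local frequency vector (`ω_kᵀ u = Δφ_k`), combined per voxel
  by certainty-weighted least squares and accumulated with certainty
  weighting over 8 dyadic resolution steps (20 iterations per step, 4 on the
  final grid, field smoothing 1.25× the level's voxel size). Because phase
  carries no amplitude, the method is invariant to intensity rescaling.
* **SFBR** (salient features). Scale-space Laplacian-of-Gaussian interest
  points with sub-voxel localisation, mutual-nearest-neighbour descriptor
  matching with a ratio test and spatial gate, interpolated by a 3-D
  thin-plate spline with kernel `U(r) = r`.

ROIs travel either as binary masks pulled back through the field
(trilinear sample at `x + u(x)`, threshold 0.5, no smoothing) or as closed
triangle meshes (marching-tetrahedra isosurface) whose vertices are mapped
by a moving→fixed thin-plate spline.

Evaluation: Dice score `2|A∩B|/(|A|+|B|)`, mean slicewise Hausdorff
distance (MSHD, mm), centre-of-mass shift (cm), volume-change statistics,
one-way ANOVA at p = 0.05 and point-biserial correlation for comparing
metric distributions against ordinal physician utility scores.

Validation: a synthetic thorax phantom (two lungs, tumour, cord inside a
vertebral annulus, low-contrast esophagus and nodal volume) with analytic,
provably invertible ground-truth deformations — translations, Gaussian
bumps, radial tumour shrinkage — and a cohort generator that emulates the
published 17-patient GTV volume-change distribution (14 shrinking / 3
growing).

I/O: NIfTI-1 (`.nii`/`.nii.gz`) and MetaImage (`.mha`/`.mhd`) images, masks
and 3-component vector fields; OBJ/PLY meshes; JSON configs; CSV/JSON metric
reports. A `dirprop` command-line script (in `inst/cli/`) exposes
`register`, `propagate`, `evaluate`, `phantom`, `report` and `config`
subcommands.

## Worked example

Register a deformed phantom pair with Demons and evaluate the propagated
contours against the known ground truth (coarse 4 × 4 × 6 mm grid so the
example runs in seconds):

```r
library(dirprop)

spec <- phantom_spec(grid = image_grid(c(64, 64, 24), c(4, 4, 6)),
                     noise_sigma_hu = 10)
def  <- gt_deformation("gaussian_bump", amplitude_mm = c(4, -2, 4),
                       center = c(172, 115, 72), sigma_mm = 30)
pair <- make_deformed_pair(spec, def)

cfg <- run_config("demons", rigid = FALSE,
                  demons = demons_config(schedule = pyramid_schedule(
                    c(4L, 2L, 1L), c(100L, 60L, 30L), c(3, 3, 1.5))))
res <- run_pipeline(pair$mid$image, pair$pre$image,
                    pair$pre$rois[c("GTV", "lung-R", "cord")], cfg,
                    reference_rois = pair$mid$rois[c("GTV", "lung-R", "cord")])
print(res$report, digits = 3)
#>      roi algorithm  dice mshd_mm com_cm volume_pre_cm3 volume_prop_cm3 volume_ref_cm3
#> 1    GTV    demons 0.953    4.00 0.0149           15.0            13.6           13.0
#> 2 lung-R    demons 0.988    4.48 0.0653          656.1           665.5          665.3
#> 3   cord    demons 0.916    4.00 0.1216           16.1            15.7           13.8
```

Dice near 1 and MSHD near the in-plane voxel size mean the propagated
contour would need at most minor edits; the centre-of-mass column is the
shift a planner would see in the isocentre if the target were re-centred.
At full CT resolution (2 × 2 × 3 mm, the default `phantom_spec()`) the same
pipeline reaches Dice ≈ 0.98 (GTV), 0.999 (lungs) and 0.85–0.92 (cord)
for all three algorithms (see `tests/testthat/test-acceptance.R`).

The volume-change statistics of the published 17-patient cohort:

```r
v <- nsclc_gtv_volumes()
volume_change_table(v$pre_cm3, v$mid_cm3)$summary
#> $mean_pre 63.44   $mean_mid 56.59   $mean_percent_diff 6.1
#> $n_decrease 14    $n_increase 3     $n_increase_gt10 3
```

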