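---
title: "Deformable contour propagation for adaptive lung radiotherapy: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformable contour propagation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what each component
computes, which assumptions it makes, why the defaults are what they are,
and what a green test does and does not establish. No number quoted here is
asserted anywhere except where the test suite or the acceptance script
computes it.

## 1. The problem and the geometric model

During fractionated radiotherapy of non-small-cell lung cancer, a repeat CT
taken in the second week of treatment frequently shows a changed anatomy:
most gross tumour volumes (GTVs) shrink, a minority grow, normal organs
shift. Adapting the plan requires contours on the repeat scan. `dirprop`
propagates the pre-treatment contours automatically by deformable image
registration (DIR) and quantifies the agreement with reference contours.

All geometry lives on regular 3-D grids: the world coordinate of voxel
`(i, j, k)` (0-based) is `origin + index * spacing` in mm, and axis 3 is the
axial/slice axis used by the slicewise metrics. One convention is used
everywhere for deformations — the **pull-back** convention: the estimated
field `u` lives on the *fixed* (mid-treatment) grid and the vector at fixed
voxel `x` points to the matched pre-treatment location `x + u(x)`. This is
the natural convention for contour propagation, because filling a fixed
voxel of a propagated mask means looking *back* into the pre-treatment
mask. Every registrar emits fields in this convention; meshes, which live
in the pre-treatment frame, instead travel through a forward
(moving→fixed) thin-plate spline, and the direction of every transform is
carried as an explicit flag that propagation refuses to violate.

Interpolation is trilinear throughout (the field's interpolator is not
prescribed by the clinical protocols this package mirrors; trilinear is the
standard choice and is stated here once). Out-of-grid samples return the
minimum image value by default — an air-like fill for CT — because boundary
voxels routinely map outside the grid during registration; *inside* the
registration loops sampling is edge-clamped instead, since an air fill at a
cut anatomical boundary (e.g. a body that extends beyond the scanned
volume) would manufacture huge spurious mismatch forces.

## 2. The three registrars

### Fast-symmetric Demons

The demons update is the gradient-descent direction of the squared
intensity mismatch between the fixed image `f` and the warped moving image
`m`, symmetrised over both gradients and normalised so a step cannot exceed
the voxel scale:

    u = 2 (f − m)(∇f + ∇m) / (‖∇f + ∇m‖² + α² (f − m)²),  α = 1/mean spacing.

Defaults follow the standard clinical protocol: four pyramid levels at
8×/4×/2×/1× resolution, iteration caps 200/100/100/30, Gaussian smoothing
of the **total field** after every iteration with σ = 3/3/0.9/0.7 mm per
level, and histogram matching (64 levels, 7 match points) of the moving to
the fixed image beforehand. Two choices were genuinely open and are worth
recording:

* *Update- vs total-field smoothing.* The printed per-level sigmas could
  smooth either the incremental update (fluid-like) or the accumulated
  field (diffusion-like). We smooth the total field: it is the reading
  consistent with a single per-level σ, and it bounds the accumulated
  roughness rather than only the increments.
* *Intensity-difference gate* (`intensity_threshold_hu`, default 20 HU).
  The α-normalised step approaches its maximum `1/α` (the mean voxel
  spacing) wherever the local gradient is of the order `α·|f−m|` — which at
  coarse pyramid levels means that *sub-noise* intensity differences of a
  few HU in flat regions can produce near-maximal steps and let
  low-contrast structures drift by several millimetres. Updates are
  therefore zeroed where `|f − m|` is below a threshold chosen at the
  combined noise floor of two scans (σ√2 ≈ 21 HU for a typical 15 HU kVCT
  noise SD). Setting the threshold to 0 recovers the bare formula. The
  equivalent knob in the reference ITK demons is
  `IntensityDifferenceThreshold`.

Convergence: a level stops early when the relative MSE improvement over
five iterations falls below `convergence_tol` (default 1e-4; the clinical
protocol publishes only the caps, so the tolerance is ours).

### Morphons

Quadrature filters measure *local phase*: a complex-valued filter response
`q` whose argument advances with position across an edge, independent of
the edge's contrast. Six polar-separable filters are built directly in the
frequency domain — a log-normal radial profile with centre frequency π/4
rad/voxel and 2-octave bandwidth, times a single-sided `cos²` directional
profile along the six icosahedral half-axes — which is the standard
construction for this method (spatially truncated kernels are a
discretisation of the same filters; the frequency-domain route is exact up
to the periodic boundary).

For each filter `k`, the phase difference `Δφ_k = arg(q_f · conj(q_w))`
between fixed and warped-moving responses constrains the displacement.
The naive constraint `ρ n_kᵀ u = Δφ_k` (filter direction times nominal
centre frequency) is orientation-biased: for a 1-D structure *every*
responding filter measures the same `ωᵀu`, where `ω` is the structure's
frequency vector, not a displacement along its own axis — solving the
weighted least squares with the naive constraints overshoots a pure
sinusoid's shift by ~20%. We therefore use each filter's **local frequency
vector** `ω_k = ∇arg(q_f)` (computed as `Im(conj(q)∇q)/|q|²`, which needs
no phase unwrapping, with spectral derivatives so the estimate is exact for
band-limited signals) and the constraints `ω_kᵀ u = Δφ_k`, weighted by the
certainty `c_k = |q_f conj(q_w)| · cos²(Δφ_k/2)`. The suite pins this with
an analytic oracle: a sinusoid of frequency π/4 shifted by 1.5 voxels is
recovered within 5%, axis-aligned and oblique.

Updates accumulate with certainty weighting
(`u ← u + c_u/(c_a + c_u)·Δu`, `c_a ← (c_a² + c_u²)/(c_a + c_u)`) and the
field and running certainty are smoothed with σ = 1.25 × the level's voxel
size, over 8 dyadic resolution steps with caps 20 (intermediate) and 4
(final). Phase is only identifiable within ±π, so displacements beyond
±π/ρ per level rely on the coarse levels of the pyramid — no unwrapping is
attempted. Because every quantity is linear or ratio-based in the image
amplitudes, a global intensity rescaling of either image leaves the field
bit-identical; the acceptance suite asserts the < 0.1 voxel RMS bound and
the qualitative ordering against Demons run without histogram matching.

### Salient-feature-based registration (SFBR)

The commercial original of this approach is unpublished; the package's
pipeline is a documented open stand-in, not a claim about that
implementation. Interest points are extrema of the σ³-normalised
Laplacian-of-Gaussian over space and a half-octave scale ladder (default
σ = 3 mm × 2^(j/2), 6 scales), localised to sub-voxel precision by a
per-axis quadratic fit, cleaned by a boundary margin (the frequency-domain
filtering is periodic), an absolute response threshold (10 HU), a relative
threshold (10% of the image's strongest response, suppressing the LoG
side-ring), non-maximum suppression at 6 mm, and a strongest-N cap
(default 1500, inside the 1000–2000 range typical for feature-based DIR of
a thorax). For a 3-D Gaussian blob of width σ_b the σ³-normalised response
peaks at σ = σ_b√(3/2), so the reported feature scale √2·σ_det equals
σ_b√3 — the suite verifies this relation numerically.

Descriptors are an 8-bin normalised local intensity histogram plus the
normalised projections of the mean absolute gradient onto the six
icosahedral axes, over a neighbourhood of 2× the feature scale. Matching is
mutual-nearest-neighbour in descriptor space, gated by a 30 mm maximum
displacement (post rigid alignment) and Lowe's ratio test (0.8; a feature
with no second in-gate neighbour passes for any positive ratio and fails
for ratio 0).

The correspondences are interpolated by a 3-D thin-plate spline with the
biharmonic kernel `U(r) = r` — not the 2-D `r² log r` form. Two numerical
points matter. First, `U(r) = r` is conditionally *negative* definite, so
spline ridge regularisation must *subtract* λ from the kernel diagonal
(`K − λI`); adding it moves the bordered system towards singularity, which
shows up as exploding weights and non-monotone bending energy around
λ ≈ 10 on random landmark sets. With the correct sign the bending energy
`−Σ_c w_cᵀ K w_c` is non-negative, zero exactly for affine maps, and
monotone non-increasing in λ, all of which the suite asserts. Second, two
TPS fits are produced: fixed→moving (the pull-back map, from which a
displacement field can be sampled) and moving→fixed on the reversed
correspondences — pre-treatment mesh vertices live in the moving frame, so
mesh propagation *must* use the forward fit, and the direction flag is
checked at the call site. Default λ = 0.01 mm damps noisy correspondences;
λ = 0 gives exact interpolation.

### Rigid pre-alignment

All registrars assume rigid pre-alignment. "Local correlation" is
implemented as the mean of normalised cross-correlations over a cubic block
decomposition of the fixed image (default 16³ voxels; blocks with intensity
SD below 20 HU are discarded as structureless, and at least three usable
blocks are required). The 6-parameter optimum is found by seeded multi-start
coordinate descent with shrinking steps, followed by a Nelder–Mead polish —
coordinate descent alone stalls on diagonal ridges where a rotation and its
compensating translation must move together. The accepted-objective trace
is exposed and asserted non-decreasing. Whether the reference workflow
optimised rotations at all is unknown; both modes are supported and
rotations are on by default.

## 3. Propagation and metrics

Masks: each fixed voxel samples the pre-treatment binary mask trilinearly
at `x + u(x)` and is labelled 1 iff the value is ≥ 0.5 — the unbiased
iso-level for binary data; no morphological smoothing is applied
afterwards, by design. Meshes: marching tetrahedra extract the 0.5
isosurface of the binary mask (six tetrahedra per cell sharing a main
diagonal, vertices at edge midpoints), which is watertight by construction
and approximates the same trilinear level set the mask route thresholds;
vertices are mapped through the forward TPS and the mesh is voxelised by
ray-parity with jittered ray origins.

Dice is the printed voxel-count formula; two empty masks are defined to
agree (Dice 1, with a warning). The MSHD is the mean over axial slices —
where **both** masks are present — of the symmetric Hausdorff distance
between the in-plane boundary voxel-centre point sets (2-D distances in
world mm). Slices where only one mask is present are excluded from the mean
by default and counted in an attribute; a fixed penalty distance is
available instead, because any particular penalty would be arbitrary.
Whether the original analysis used voxel centres or sub-voxel contour
polygons is unstated; the voxel-centre convention is documented here and
the implementation is required by the tests to match an exhaustive
all-pairs oracle exactly. The centre-of-mass distance is between unweighted
voxel centroids, reported in cm. The ANOVA is the classical between/within
mean-square F with its F-distribution p-value (threshold 0.05), and the
point-biserial correlation uses the population-SD form, making it exactly
the Pearson correlation of the values with the 0/1 indicator; physician
utility scores map 1 → class 0 ("no edits") and {2, 3} → class 1.

## 4. The phantom: what it emulates, and what a green test establishes

The phantom is an analytic thorax on a 128 × 128 × 48 grid at 2 × 2 × 3 mm:
an elliptical body (0 HU) in air (−1000), two lung ellipsoids (−750), a
40 HU tumour sphere (radius 15 mm) inside the right lung, a spinal cord
(60 HU, radius 5 mm) inside a 500 HU vertebral annulus, and deliberately
low-contrast esophagus and nodal structures (+15 HU against mediastinum) —
mirroring the fact that kVCT soft-tissue contrast around those structures
is poor, which is exactly where clinical propagation is weakest. White
Gaussian noise (default SD 15 HU, a typical kVCT value) is added from a
seeded generator; a fixed seed gives bit-identical phantoms.

Images are rasterised with 2×2×2 stratified supersampling, i.e.
partial-volume edges. This matters: hard point sampling makes a binary
500 HU edge flip entire voxels under a 0.1 mm true displacement — aliasing
"salt" with no counterpart in band-limited real CT — and that artifact,
not noise, dominated registration error in early experiments. ROI masks,
by contrast, are exact point-in-shape tests at voxel centres, so the ground
truth against which propagation is scored carries no interpolation bias.

Ground-truth deformations are analytic pull-back maps `φ(x) = x + u(x)`:
translations; Gaussian bumps (`a·exp(−|x−c|²/2σ²)`, invertible while
`|a| < σ√e`); and radial tumour shrinkage, which scales radii by `1/s`
inside an inner radius and blends smoothly to the identity — so a tumour of
linear size `r` appears with size `s·r` mid-treatment and the volume scales
as `s³`. Sampling a deformation asserts a positive discrete Jacobian
determinant everywhere. The mid-treatment image and ROIs are **re-rasterised
from the deformed analytic scene**, never produced by resampling, keeping
the ground truth independent of the propagation code under test. The
cohort generator draws per-case volume changes from the published
17-patient distribution (14 shrinking, 3 growing) and realises each as a
radial shrink with linear scale `(1 − pct/100)^(1/3)`.

What the phantom does *not* emulate: respiratory motion, correlated CT
noise texture (quantum noise, streaks), sliding interfaces (lung/chest
wall), topology changes, and — most importantly — the observer variability
and PET-informed redefinition of target volumes that drive part of the
disagreement between propagated and physician-drawn contours on real
patients. A green deformation-recovery test therefore establishes that the
algorithms recover a smooth, invertible, moderate deformation on
CT-like contrast; it does not predict clinical Dice values.

Two quantisation effects bound what contour agreement is achievable at all
on a 2 × 2 × 3 mm grid, independent of registration quality: (i) the
re-rasterised mid ROI and the warp-and-threshold propagated ROI each carry
an independent half-voxel staircase on their boundary shell, which caps the
agreement of a 15 mm sphere near Dice 0.96 and an 8 mm sphere near 0.95
even under the *true* field (lung-scale ROIs reach 0.99); and (ii) thin
z-uniform cylinders such as the cord are knife-edge degenerate — a
sub-0.1 mm displacement can flip the same boundary voxels on every slice.
The tests assert the geometry-appropriate floors and pin the propagation
arithmetic itself with an exact per-voxel brute-force oracle.

## 5. Numerical choices

* Gaussian smoothing and the quadrature/LoG filters run in the DFT domain
  (continuous transfer functions sampled on the grid), so boundary handling
  is circular; detection margins and the air background make this benign,
  and the σ→∞ limit reproducing the mean exactly is tested.
* `histogram_match` takes its quantiles from 64-bin histogram CDFs of the
  *foreground* (voxels above the image mean — the ITK-style behaviour that
  keeps CT's dominant air peak from crushing the match points), anchors the
  extreme knots at the global min/max, and enforces a monotone map.
* The symmetric demons denominator gates at 1e-9; degenerate voxels get a
  zero update. Field upsampling between levels interpolates mm vectors
  componentwise (magnitudes are resolution-independent).
* Morphons' per-voxel 3×3 normal equations are solved in closed form with a
  Tikhonov floor proportional to the local certainty, which cancels under
  global intensity rescaling and so preserves exact invariance.
* Mesh voxelisation jitters ray origins by ~1e-4 of a voxel to avoid
  edge-through-vertex parity errors; TPS evaluation is chunked (4000 points)
  to bound memory.
* Determinism: the only random number generators are the phantom's (seeded
  in its spec) and the rigid optimiser's multi-start (seed in its config,
  default 0; the global RNG state is saved and restored). Identical inputs
  and configs give bit-identical fields for all three registrars.

## 6. Known limitations

* No diffeomorphic/log-domain variant and no inverse-consistency
  enforcement; invertibility is asserted for the *ground truth*, not for
  estimated fields.
* SFBR's detector/descriptor/matcher is an open reconstruction of an
  unpublished commercial method; feature counts and match quality on real
  patient data will differ.
* The MSHD voxel-centre convention slightly overestimates distances for
  sub-voxel contour differences compared with polygonal contours.
* DICOM / DICOM-RT, 4-D containers and oblique (rotated) NIfTI/MetaImage
  orientations are out of scope; only axis-aligned geometries are read and
  written.
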