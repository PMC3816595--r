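# Synthetic thorax phantom: analytic geometry (body, two lungs, tumour,
# spinal cord inside a vertebral annulus, low-contrast esophagus and nodal
# volume) rasterised onto a CT-like grid, plus smooth analytic ground-truth
# deformations.  Mid-treatment images and ROIs are produced by evaluating
# the analytic scene at the pulled-back point x + u(x) - i.e. by
# re-rasterising deformed geometry - so the ground truth carries no
# interpolation bias and is independent of the propagation code under test.

#' Phantom specification
#'
#' All geometry is in world mm on the phantom grid (default 128 x 128 x 48
#' voxels at 2 x 2 x 3 mm, a 256 x 256 x 144 mm thorax field of view).
#' Intensities approximate HU: air -1000, body/soft tissue 0, lungs -750,
#' tumour 40, cord 60 inside a 500 HU vertebral annulus, and deliberately
#' low-contrast esophagus and nodal volumes (+15 HU against mediastinum),
#' mirroring the poor kVCT soft-tissue contrast around those structures.
#'
#' @param grid phantom `image_grid`.
#' @param noise_sigma_hu additive Gaussian noise SD (HU).
#' @param supersample images are rasterised with this many stratified
#'   sub-samples per voxel axis and box-averaged (partial-volume edges,
#'   emulating the scanner's band-limiting PSF; 1 = hard point sampling).
#'   ROI masks are always exact point-in-shape tests at voxel centres.
#' @param seed RNG seed; a fixed seed gives bit-identical phantoms.
#' @param tumour_center,tumour_radius GTV sphere (mm).
#' @param organs optional full override of the organ geometry list.
#' @export
phantom_spec <- function(grid = image_grid(c(128L, 128L, 48L), c(2, 2, 3)),
                         noise_sigma_hu = 15, supersample = 2L, seed = 0L,
                         tumour_center = c(172, 115, 72),
                         tumour_radius = 15,
                         organs = NULL) {
  if (is.null(organs)) {
    organs <- list(
      body  = list(type = "ellipse_cyl", center = c(127, 127),
                   semi = c(110, 85), hu = 0),
      `lung-L` = list(type = "ellipsoid", center = c(69, 115, 70.5),
                      semi = c(45, 58, 60), hu = -750),
      `lung-R` = list(type = "ellipsoid", center = c(185, 115, 70.5),
                      semi = c(45, 58, 60), hu = -750),
      vertebra = list(type = "annulus_cyl", center = c(127, 192),
                      r_inner = 7, r_outer = 15, hu = 500),
      cord  = list(type = "circle_cyl", center = c(127, 192), r = 5, hu = 60),
      esophagus = list(type = "circle_cyl", center = c(127, 160), r = 5,
                       hu = 15),
      `nodal-GTV` = list(type = "sphere", center = c(127, 135, 78), r = 8,
                         hu = 15),
      GTV = list(type = "sphere", center = tumour_center, r = tumour_radius,
                 hu = 40))
  }
  spec <- structure(list(grid = grid, noise_sigma_hu = noise_sigma_hu,
                         supersample = max(1L, as.integer(supersample)),
                         seed = as.integer(seed), organs = organs),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

# inside test for one organ at points (n x 3 world mm)
organ_inside <- function(organ, pts) {
  switch(organ$type,
    ellipse_cyl = ((pts[, 1] - organ$center[1]) / organ$semi[1])^2 +
                  ((pts[, 2] - organ$center[2]) / organ$semi[2])^2 <= 1,
    ellipsoid = ((pts[, 1] - organ$center[1]) / organ$semi[1])^2 +
                ((pts[, 2] - organ$center[2]) / organ$semi[2])^2 +
                ((pts[, 3] - organ$center[3]) / organ$semi[3])^2 <= 1,
    circle_cyl = (pts[, 1] - organ$center[1])^2 +
                 (pts[, 2] - organ$center[2])^2 <= organ$r^2,
    annulus_cyl = {
      r2 <- (pts[, 1] - organ$center[1])^2 + (pts[, 2] - organ$center[2])^2
      r2 >= organ$r_inner^2 & r2 <= organ$r_outer^2
    },
    sphere = (pts[, 1] - organ$center[1])^2 + (pts[, 2] - organ$center[2])^2 +
             (pts[, 3] - organ$center[3])^2 <= organ$r^2,
    stop("unknown organ type ", organ$type))
}

# noise-free analytic intensity at points; organs listed later override
# earlier ones (tumour over lung, cord over vertebra, ...)
phantom_intensity <- function(spec, pts) {
  hu <- rep(-1000, nrow(pts))
  for (organ in spec$organs) hu[organ_inside(organ, pts)] <- organ$hu
  hu
}

validate_phantom_spec <- function(spec) {
  o <- spec$organs
  probe <- function(organ) {
    # coarse point cloud on the organ's bounding region
    ctr <- organ$center
    r <- switch(organ$type, sphere = organ$r, circle_cyl = organ$r,
                annulus_cyl = organ$r_outer,
                ellipsoid = max(organ$semi), ellipse_cyl = max(organ$semi))
    if (length(ctr) == 2L) ctr <- c(ctr, mean(range(grid_points(spec$grid)[, 3])))
    g <- as.matrix(expand.grid(seq(-r, r, length.out = 7),
                               seq(-r, r, length.out = 7),
                               seq(-r, r, length.out = 7)))
    sweep(g, 2, ctr, "+")
  }
  gtv <- o$GTV
  pts <- probe(gtv)
  in_gtv <- organ_inside(gtv, pts)
  if (!any(organ_inside(o$body, pts[in_gtv, , drop = FALSE])))
    stop("tumour lies outside the body")
  for (bad in c("cord", "vertebra", "esophagus")) {
    if (!is.null(o[[bad]]) && any(in_gtv & organ_inside(o[[bad]], pts)))
      stop("overlapping incompatible organs: GTV and ", bad)
  }
  invisible(spec)
}

#' Rasterise a phantom
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (`scalar_image`, noise added from the seeded
#'   generator) and `rois` (named list of noise-free analytic `roi_mask`s:
#'   GTV, nodal-GTV, lung-L, lung-R, esophagus, cord).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  pts <- grid_points(spec$grid)
  phantom_at(spec, pts, spec$seed)
}

# shared rasteriser: evaluate scene at arbitrary (possibly deformed) points;
# image intensities are box-averaged over `supersample`^3 stratified
# sub-voxel offsets (partial-volume edges), masks stay point-sampled
phantom_at <- function(spec, pts, seed) {
  ss <- spec$supersample
  if (ss <= 1L) {
    hu <- phantom_intensity(spec, pts)
  } else {
    off1 <- ((seq_len(ss) - 0.5) / ss - 0.5)
    hu <- 0
    for (ox in off1) for (oy in off1) for (oz in off1) {
      delta <- c(ox, oy, oz) * spec$grid$spacing
      hu <- hu + phantom_intensity(spec, sweep(pts, 2, delta, "+"))
    }
    hu <- hu / ss^3
  }
  if (spec$noise_sigma_hu > 0) {
    rng <- local({ set.seed(seed); stats::rnorm(nrow(pts), 0, spec$noise_sigma_hu) })
    hu <- hu + rng
  }
  roi_names <- c("GTV", "nodal-GTV", "lung-L", "lung-R", "esophagus", "cord")
  rois <- lapply(roi_names, function(nm)
    roi_mask(array(as.integer(organ_inside(spec$organs[[nm]], pts)),
                   spec$grid$dims), spec$grid, nm))
  names(rois) <- roi_names
  list(image = scalar_image(array(hu, spec$grid$dims), spec$grid),
       rois = rois)
}

# ---------------------------------------------------------------------------
# Ground-truth deformations.  A deformation is an analytic pull-back map
# phi(x) = x + u(x) from the mid-treatment (fixed) frame into the
# pre-treatment (moving) frame; its sampled field on the phantom grid IS the
# ground-truth DVF in the package's field convention.

#' Analytic ground-truth deformation
#'
#' Kinds:
#' \describe{
#' \item{translation}{u(x) = `shift_mm` everywhere.}
#' \item{gaussian_bump}{u(x) = `amplitude_mm` * exp(-|x - center|^2 /
#'   (2 sigma_mm^2)); invertible while |amplitude| < sigma * sqrt(e).}
#' \item{radial_tumour_shrink}{radial pull-back about `center`: points
#'   within `radius_mm` are scaled by 1/`scale` (so a structure of linear
#'   size s becomes size `scale` * s in the mid frame), blending smoothly
#'   to the identity at `radius_mm + falloff_mm`.  `scale` < 1 shrinks,
#'   > 1 grows.}
#' \item{composite}{sum of the component deformations' u.}
#' }
#'
#' @param kind one of the above.
#' @param shift_mm,amplitude_mm,center,sigma_mm,scale,radius_mm,falloff_mm
#'   kind-specific parameters (mm; see above).
#' @param components list of deformations for `kind = "composite"`.
#' @return object of class `gt_deformation` with an analytic displacement
#'   function `u(pts)`.
#' @export
gt_deformation <- function(kind = c("translation", "gaussian_bump",
                                    "radial_tumour_shrink", "composite"),
                           shift_mm = c(0, 0, 0),
                           amplitude_mm = c(6, 0, 0), center = c(128, 128, 72),
                           sigma_mm = 30,
                           scale = 0.9, radius_mm = 20, falloff_mm = 25,
                           components = NULL) {
  kind <- match.arg(kind)
  u <- switch(kind,
    translation = function(pts)
      matrix(shift_mm, nrow(pts), 3, byrow = TRUE),
    gaussian_bump = function(pts) {
      r2 <- (pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2 +
            (pts[, 3] - center[3])^2
      w <- exp(-r2 / (2 * sigma_mm^2))
      cbind(w * amplitude_mm[1], w * amplitude_mm[2], w * amplitude_mm[3])
    },
    radial_tumour_shrink = function(pts) {
      dx <- sweep(pts, 2, center, "-")
      r <- sqrt(rowSums(dx^2))
      # taper T: 1 inside radius_mm, smoothstep to 0 at radius_mm+falloff_mm
      t_ <- pmin(pmax((r - radius_mm) / falloff_mm, 0), 1)
      taper <- 1 - t_^2 * (3 - 2 * t_)
      g <- 1 + (1 / scale - 1) * taper
      dx * (g - 1)
    },
    composite = {
      if (is.null(components)) stop("composite needs components")
      function(pts) Reduce(`+`, lapply(components, function(d) d$u(pts)))
    })
  structure(list(kind = kind, u = u,
                 params = list(shift_mm = shift_mm,
                               amplitude_mm = amplitude_mm, center = center,
                               sigma_mm = sigma_mm, scale = scale,
                               radius_mm = radius_mm,
                               falloff_mm = falloff_mm)),
            class = "gt_deformation")
}

#' Sample a ground-truth deformation on a grid
#'
#' Asserts invertibility: the discrete Jacobian determinant of x + u(x)
#' must be positive at every voxel.
#' @param deformation a `gt_deformation`.
#' @param grid an `image_grid`.
#' @return `displacement_field` (pull-back convention).
#' @export
sample_deformation <- function(deformation, grid) {
  u <- deformation$u(grid_points(grid))
  field <- displacement_field(array(u, c(grid$dims, 3L)), grid)
  if (min(jacobian_determinant(field)) <= 0)
    stop("non-invertible deformation (Jacobian determinant <= 0)")
  field
}

#' Deformed phantom pair with ground truth
#'
#' The pre-treatment (moving) phantom is rasterised from the analytic
#' scene; the mid-treatment (fixed) image and ROIs are rasterised from the
#' analytically deformed scene, i.e. scene values at phi(x) = x + u(x).
#' Both image noises are drawn independently (seed and seed + 1000).
#'
#' @param spec a [phantom_spec()].
#' @param deformation a [gt_deformation()].
#' @return list(pre, mid, true_field): `pre`/`mid` as returned by
#'   [make_phantom()], `true_field` the sampled ground-truth DVF on the
#'   phantom grid.
#' @export
make_deformed_pair <- function(spec = phantom_spec(),
                               deformation = gt_deformation("gaussian_bump")) {
  true_field <- sample_deformation(deformation, spec$grid)
  pts <- grid_points(spec$grid)
  pre <- phantom_at(spec, pts, spec$seed)
  mid <- phantom_at(spec, pts + deformation$u(pts), spec$seed + 1000L)
  list(pre = pre, mid = mid, true_field = true_field)
}

#' Generate a phantom cohort emulating an observed volume-change distribution
#'
#' Builds `n` pre/mid phantom pairs whose tumour volume changes are drawn
#' (without replacement while available, seeded) from a target list of
#' percent differences - by default the published 17-patient NSCLC cohort
#' (14 shrinking, 3 growing GTVs; see [nsclc_gtv_volumes()]).  Each case's
#' deformation is a radial tumour shrink with linear scale
#' (1 - pct/100)^(1/3).
#'
#' @param n number of cases.
#' @param seed RNG seed.
#' @param spec phantom spec shared by the cases.
#' @param target_pct percent-difference pool to emulate.
#' @param keep_pairs return the full image pairs (memory-heavy) or only the
#'   manifest plus deformations.
#' @return list(manifest, cases): manifest is a data.frame(case, pct_target,
#'   scale_linear, vol_pre_cm3, vol_mid_cm3, pct_measured); cases a list
#'   with the deformation (and the pair when `keep_pairs`).
#' @export
generate_cohort <- function(n, seed = 0L, spec = phantom_spec(),
                            target_pct = {
                              v <- nsclc_gtv_volumes()
                              round(100 * (v$pre_cm3 - v$mid_cm3) / v$pre_cm3, 1)
                            },
                            keep_pairs = FALSE) {
  if (n < 1L) stop("n must be >= 1")
  set.seed(seed)
  pct <- if (n <= length(target_pct)) sample(target_pct, n)
         else sample(target_pct, n, replace = TRUE)
  gtv <- spec$organs$GTV
  rows <- vector("list", n)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    s_lin <- (1 - pct[i] / 100)^(1 / 3)
    def <- gt_deformation("radial_tumour_shrink", center = gtv$center,
                          scale = s_lin,
                          radius_mm = max(s_lin, 1) * gtv$r + 4,
                          falloff_mm = 25)
    spec_i <- spec
    spec_i$seed <- spec$seed + i
    pair <- make_deformed_pair(spec_i, def)
    v_pre <- mask_volume_cm3(pair$pre$rois$GTV)
    v_mid <- mask_volume_cm3(pair$mid$rois$GTV)
    rows[[i]] <- data.frame(case = i, pct_target = pct[i],
                            scale_linear = s_lin, vol_pre_cm3 = v_pre,
                            vol_mid_cm3 = v_mid,
                            pct_measured = 100 * (v_pre - v_mid) / v_pre)
    cases[[i]] <- if (keep_pairs) list(deformation = def, pair = pair)
                  else list(deformation = def)
  }
  list(manifest = do.call(rbind, rows), cases = cases)
}
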