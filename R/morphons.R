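# Morphons registration: displacement updates driven by local phase
# differences of complex quadrature-filter responses, combined across six
# filter directions by certainty-weighted least squares.  Because phase is
# insensitive to intensity scale, the registrar is invariant to global
# intensity rescaling of either image.

#' Quadrature filter bank
#'
#' Six polar-separable quadrature filters built in the frequency domain:
#' log-normal radial profile R(w) = exp(-4/(B^2 ln 2) * ln^2(|w|/rho))
#' with centre frequency `rho` (rad/voxel) and relative bandwidth `B`
#' octaves, times a single-sided directional profile (w_hat . n_k)^2 for
#' w . n_k > 0 along the six icosahedral half-axes n_k.
#'
#' @param center_frequency centre frequency rho, rad/voxel.
#' @param bandwidth_octaves relative bandwidth B.
#' @return object of class `quadrature_filter_bank` holding the directions;
#'   frequency-domain kernels are realised per grid by
#'   `bank_transfer_functions()`.
#' @export
quadrature_filter_bank <- function(center_frequency = pi / 4,
                                   bandwidth_octaves = 2) {
  phi <- (1 + sqrt(5)) / 2
  dirs <- rbind(c(1, phi, 0), c(phi, 0, 1), c(0, 1, phi),
                c(1, -phi, 0), c(phi, 0, -1), c(0, -1, phi))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  structure(list(directions = dirs,
                 center_frequency = center_frequency,
                 bandwidth_octaves = bandwidth_octaves),
            class = "quadrature_filter_bank")
}

# frequency-domain transfer functions of the bank on a given array dim
# (voxel-unit frequencies); returns list of complex arrays
bank_transfer_functions <- function(bank, dims) {
  wx <- 2 * pi * fft_freq(dims[1], 1)
  wy <- 2 * pi * fft_freq(dims[2], 1)
  wz <- 2 * pi * fft_freq(dims[3], 1)
  WX <- array(wx, dims)
  WY <- array(rep(wy, each = dims[1]), dims)
  WZ <- array(rep(wz, each = dims[1] * dims[2]), dims)
  wn <- sqrt(WX^2 + WY^2 + WZ^2)
  rho <- bank$center_frequency
  B <- bank$bandwidth_octaves
  radial <- array(0, dims)
  nz <- wn > 0
  radial[nz] <- exp(-4 / (B^2 * log(2)) * log(wn[nz] / rho)^2)
  lapply(seq_len(nrow(bank$directions)), function(k) {
    n <- bank$directions[k, ]
    proj <- WX * n[1] + WY * n[2] + WZ * n[3]
    dirprof <- ifelse(proj > 0, (proj / pmax(wn, 1e-12))^2, 0)
    radial * dirprof
  })
}

# complex filter responses of a real image (one fft, one ifft per filter)
quadrature_responses <- function(values, tfs) {
  Fv <- fft(values)
  lapply(tfs, function(H) {
    q <- fft(Fv * H, inverse = TRUE) / length(values)
    dim(q) <- dim(values)
    q
  })
}

# fixed-image phase structure: per filter the complex response q and the
# local frequency vector w = Im(Conj(q) grad q)/|q|^2 (rad/voxel), with
# grad q taken spectrally (exact for band-limited responses) and |w|
# clamped to [rho/4, 4 rho]
fixed_phase_struct <- function(values, bank, tfs) {
  d <- dim(values)
  N <- length(values)
  Fv <- fft(values)
  WX <- array(2 * pi * fft_freq(d[1], 1), d)
  WY <- array(rep(2 * pi * fft_freq(d[2], 1), each = d[1]), d)
  WZ <- array(rep(2 * pi * fft_freq(d[3], 1), each = d[1] * d[2]), d)
  rho <- bank$center_frequency
  lapply(tfs, function(H) {
    Q <- Fv * H
    ift <- function(z) { r <- fft(z, inverse = TRUE) / N; dim(r) <- d; r }
    q <- ift(Q)
    qmod2 <- Mod(q)^2
    den <- qmod2 + 1e-12 * max(qmod2, 1e-300)
    w1 <- Im(Conj(q) * ift(Q * (1i * WX))) / den
    w2 <- Im(Conj(q) * ift(Q * (1i * WY))) / den
    w3 <- Im(Conj(q) * ift(Q * (1i * WZ))) / den
    wmag <- sqrt(w1^2 + w2^2 + w3^2)
    fac <- pmin(pmax(wmag, rho / 4), 4 * rho) / pmax(wmag, 1e-12)
    list(q = q, w1 = w1 * fac, w2 = w2 * fac, w3 = w3 * fac)
  })
}

#' Morphons configuration
#'
#' Defaults follow the printed multi-resolution setup: 8 dyadic resolution
#' steps with the finest equal to the full CT resolution, at most 20
#' iterations per step and 4 on the final grid, and Gaussian field
#' smoothing with sigma 1.25 times the voxel size of the resolution grid.
#'
#' @param levels number of dyadic resolution steps.
#' @param max_iterations_per_level iteration cap on all but the final level.
#' @param max_iterations_final iteration cap on the final (full-resolution)
#'   level.
#' @param smoothing_sigma_factor field-smoothing sigma as a multiple of the
#'   level's voxel size.
#' @param bank a [quadrature_filter_bank()].
#' @param max_step_mm cap on a single phase-derived update step (mm).
#' @export
morphons_config <- function(levels = 8L, max_iterations_per_level = 20L,
                            max_iterations_final = 4L,
                            smoothing_sigma_factor = 1.25,
                            bank = quadrature_filter_bank(),
                            max_step_mm = 4) {
  structure(list(levels = as.integer(levels),
                 max_iterations_per_level = as.integer(max_iterations_per_level),
                 max_iterations_final = as.integer(max_iterations_final),
                 smoothing_sigma_factor = smoothing_sigma_factor,
                 bank = bank, max_step_mm = max_step_mm),
            class = "morphons_config")
}

#' Phase-difference displacement update
#'
#' For each filter direction k the local phase difference of the complex
#' responses, dphi_k = Arg(q_fixed * Conj(q_warped)), constrains the
#' displacement through the filter's local frequency vector
#' w_k = grad arg(q_fixed) (rad/voxel, computed as
#' Im(Conj(q) grad q) / |q|^2, which needs no phase unwrapping):
#' w_k' u = dphi_k, weighted by the certainty
#' c_k = |q_fixed * Conj(q_warped)| * cos^2(dphi_k / 2).  Using the local
#' frequency instead of the nominal rho n_k removes the orientation bias
#' of the naive directional constraint: for a 1-D structure every
#' responding filter measures the same w' u, and the weighted
#' least-squares solution recovers the true shift.  Frequency magnitudes
#' are clamped to [rho/4, 4 rho]; voxels with vanishing total certainty
#' get a zero update.
#'
#' @param fixed,warped `scalar_image`s on the same grid.
#' @param bank a [quadrature_filter_bank()].
#' @param max_step_mm update magnitude cap (mm).
#' @param fixed_struct precomputed fixed-image phase structure (internal;
#'   lets the registrar reuse it across iterations of a level).
#' @return list(update = `displacement_field` (mm), certainty = array).
#' @export
phase_difference_update <- function(fixed, warped,
                                    bank = quadrature_filter_bank(),
                                    max_step_mm = Inf,
                                    fixed_struct = NULL, tfs = NULL) {
  if (!grids_equal(fixed$grid, warped$grid)) stop("images must share a grid")
  d <- fixed$grid$dims
  if (is.null(tfs)) tfs <- bank_transfer_functions(bank, d)
  if (is.null(fixed_struct))
    fixed_struct <- fixed_phase_struct(fixed$values, bank, tfs)
  qw <- quadrature_responses(warped$values, tfs)
  # weighted normal equations A u = b over constraints w_k' u = dphi_k
  A11 <- A12 <- A13 <- A22 <- A23 <- A33 <- array(0, d)
  b1 <- b2 <- b3 <- array(0, d)
  ctot <- array(0, d)
  for (k in seq_along(fixed_struct)) {
    fs <- fixed_struct[[k]]
    pr <- fs$q * Conj(qw[[k]])
    dphi <- Arg(pr)
    ck <- Mod(pr) * cos(dphi / 2)^2
    w1 <- fs$w1; w2 <- fs$w2; w3 <- fs$w3
    A11 <- A11 + ck * w1 * w1; A12 <- A12 + ck * w1 * w2
    A13 <- A13 + ck * w1 * w3; A22 <- A22 + ck * w2 * w2
    A23 <- A23 + ck * w2 * w3; A33 <- A33 + ck * w3 * w3
    b1 <- b1 + ck * dphi * w1; b2 <- b2 + ck * dphi * w2
    b3 <- b3 + ck * dphi * w3
    ctot <- ctot + ck
  }
  # Tikhonov floor keeps the 3x3 solves well-posed; relative to the local
  # certainty so it cancels under global intensity rescaling
  eps <- 1e-6 * (ctot + 1e-300)
  A11 <- A11 + eps; A22 <- A22 + eps; A33 <- A33 + eps
  det_ <- A11 * (A22 * A33 - A23^2) - A12 * (A12 * A33 - A23 * A13) +
    A13 * (A12 * A23 - A22 * A13)
  inv_ok <- abs(det_) > 1e-300 & ctot > 1e-12 * max(ctot, 1e-300)
  det_[!inv_ok] <- 1
  ux <- ((A22 * A33 - A23^2) * b1 + (A13 * A23 - A12 * A33) * b2 +
         (A12 * A23 - A13 * A22) * b3) / det_
  uy <- ((A23 * A13 - A12 * A33) * b1 + (A11 * A33 - A13^2) * b2 +
         (A12 * A13 - A11 * A23) * b3) / det_
  uz <- ((A12 * A23 - A13 * A22) * b1 + (A13 * A12 - A11 * A23) * b2 +
         (A11 * A22 - A12^2) * b3) / det_
  ux[!inv_ok] <- 0; uy[!inv_ok] <- 0; uz[!inv_ok] <- 0
  # voxel-unit update -> world mm
  sp <- fixed$grid$spacing
  ux <- ux * sp[1]; uy <- uy * sp[2]; uz <- uz * sp[3]
  mag <- sqrt(ux^2 + uy^2 + uz^2)
  over <- mag > max_step_mm
  if (any(over)) {
    shrink <- ifelse(over, max_step_mm / pmax(mag, 1e-12), 1)
    ux <- ux * shrink; uy <- uy * shrink; uz <- uz * shrink
  }
  v <- array(0, c(d, 3L))
  v[, , , 1] <- ux; v[, , , 2] <- uy; v[, , , 3] <- uz
  list(update = displacement_field(v, fixed$grid), certainty = ctot)
}

# dyadic pyramid level grids for morphons (dims clamped to >= 4 voxels)
morphons_level_grids <- function(grid, levels) {
  factors <- 2^(seq.int(levels - 1L, 0L))
  usable <- factors <= max(grid$dims) / 4
  usable[length(factors)] <- TRUE
  if (!all(usable))
    warning(sprintf("image too small for %d dyadic levels: truncated to %d",
                    levels, sum(usable)))
  lapply(factors[usable], function(f) {
    g <- downsample_grid(grid, f)
    image_grid(pmax(g$dims, pmin(grid$dims, 4L)), g$spacing, g$origin)
  })
}

#' Morphons registration
#'
#' Multi-resolution local-phase registration: per dyadic level the moving
#' image is warped through the accumulated field, a phase-difference update
#' with certainty is computed, accumulated into the total field by
#' certainty-weighted averaging
#' (u <- u + c_u/(c_a + c_u) * du; c_a <- (c_a^2 + c_u^2)/(c_a + c_u)),
#' and field and certainty are Gaussian-smoothed with sigma =
#' `smoothing_sigma_factor` times the level's voxel size.
#'
#' @param fixed mid-treatment `scalar_image` (defines the output grid).
#' @param moving pre-treatment `scalar_image`, rigidly pre-aligned.
#' @param config a [morphons_config()].
#' @param verbose print per-level info.
#' @return `displacement_field` on the fixed grid (pull-back convention).
#' @export
morphons_register <- function(fixed, moving, config = morphons_config(),
                              verbose = FALSE) {
  grids <- morphons_level_grids(fixed$grid, config$levels)
  nlev <- length(grids)
  field <- NULL
  cert_acc <- NULL
  for (lev in seq_len(nlev)) {
    g <- grids[[lev]]
    final <- lev == nlev
    smooth_for_level <- function(img) {
      if (all(g$dims == img$grid$dims)) return(img)
      f_eff <- g$spacing / img$grid$spacing
      sm <- smooth_gaussian(img$values, 0.5 * f_eff * img$grid$spacing,
                            img$grid$spacing)
      resample_to_grid(scalar_image(sm, img$grid), g)
    }
    f_l <- smooth_for_level(fixed)
    m_l <- smooth_for_level(moving)
    if (is.null(field)) {
      field <- zero_field(g)
      cert_acc <- array(0, g$dims)
    } else {
      field <- resample_field(field, g)
      cert_acc <- array(trilinear_sample(
        scalar_image(cert_acc, grids[[lev - 1L]]), grid_points(g),
        extrapolate = "clamp"), g$dims)
    }
    sigma_mm <- config$smoothing_sigma_factor * g$spacing
    n_iter <- if (final) config$max_iterations_final
              else config$max_iterations_per_level
    tfs <- bank_transfer_functions(config$bank, g$dims)
    fstruct <- fixed_phase_struct(f_l$values, config$bank, tfs)
    for (it in seq_len(n_iter)) {
      warped <- warp_pullback(m_l, field, extrapolate = "clamp")
      upd <- phase_difference_update(f_l, warped, config$bank,
                                     config$max_step_mm,
                                     fixed_struct = fstruct, tfs = tfs)
      cu <- upd$certainty
      wgt <- cu / (cert_acc + cu + 1e-300)
      for (c_ in 1:3)
        field$vectors[, , , c_] <- field$vectors[, , , c_] +
          wgt * upd$update$vectors[, , , c_]
      cert_acc <- (cert_acc^2 + cu^2) / (cert_acc + cu + 1e-300)
      field <- smooth_field(field, sigma_mm)
      cert_acc <- smooth_gaussian(cert_acc, sigma_mm, g$spacing)
    }
    if (verbose)
      message(sprintf("morphons level %d/%d (%dx%dx%d): %d iterations",
                      lev, nlev, g$dims[1], g$dims[2], g$dims[3], n_iter))
  }
  field
}
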