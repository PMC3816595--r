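# Shared registration preprocessing: multi-resolution pyramids, rigid
# pre-alignment by blockwise local correlation, and quantile histogram
# matching.

#' Multi-resolution pyramid schedule
#'
#' @param factors integer downsampling factors, coarse to fine, strictly
#'   decreasing and ending at 1.
#' @param iterations per-level maximum iteration counts.
#' @param sigmas_mm per-level Gaussian field-smoothing sigmas (mm).
#' @export
pyramid_schedule <- function(factors, iterations, sigmas_mm) {
  factors <- as.integer(factors)
  if (length(factors) != length(iterations) ||
      length(factors) != length(sigmas_mm))
    stop("factors, iterations and sigmas_mm must have equal length")
  if (any(diff(factors) >= 0) && length(factors) > 1)
    stop("factors must be strictly decreasing")
  if (factors[length(factors)] != 1L) stop("factors must end at 1")
  if (any(iterations < 0)) stop("iterations must be >= 0")
  if (any(sigmas_mm < 0)) stop("sigmas must be >= 0")
  structure(list(factors = factors, iterations = as.integer(iterations),
                 sigmas_mm = as.numeric(sigmas_mm)),
            class = "pyramid_schedule")
}

#' Gaussian anti-aliased image pyramid
#'
#' Level k is the input smoothed with sigma = 0.5 * factor * spacing (per
#' axis) and resampled onto the factor-k grid; the finest level (factor 1)
#' is the original image.  Levels whose downsampled extent would fall below
#' 4 voxels on an axis are clamped to 4 with a warning.
#'
#' @param image a `scalar_image`.
#' @param schedule a `pyramid_schedule`.
#' @return list of `scalar_image`, coarse to fine.
#' @export
build_pyramid <- function(image, schedule) {
  lapply(schedule$factors, function(f) {
    if (f == 1L) return(image)
    g <- downsample_grid(image$grid, f)
    if (any(g$dims < 4L)) {
      warning(sprintf("pyramid level factor %d clamped to >= 4 voxels per axis", f))
      g <- image_grid(pmax(g$dims, 4L), g$spacing, g$origin)
    }
    sm <- smooth_gaussian(image$values, 0.5 * f * image$grid$spacing,
                          image$grid$spacing)
    resample_to_grid(scalar_image(sm, image$grid), g)
  })
}

#' Histogram matching by piecewise-linear quantile mapping
#'
#' Remaps the moving image's intensities so that its quantiles at
#' `match_points` interior points equal the reference image's.  Quantiles
#' are taken from `levels`-bin histograms (linear interpolation within a
#' bin) of the foreground voxels only - voxels above each image's mean
#' intensity, which for CT excludes the dominant air background (the
#' standard ITK-style behaviour); the global minima/maxima anchor the
#' extreme knots so background intensities pass through sensibly.  The
#' mapping is monotone non-decreasing.  Defaults follow common DIR
#' practice for CT: 64 levels and 7 match points.
#'
#' @param moving `scalar_image` to remap.
#' @param reference `scalar_image` whose histogram is the target.
#' @param levels number of histogram bins (>= match_points).
#' @param match_points number of interior quantile match points (>= 1).
#' @param threshold_at_mean exclude voxels below the image mean from the
#'   quantile computation (default TRUE).
#' @return remapped `scalar_image` on the moving grid.
#' @export
histogram_match <- function(moving, reference, levels = 64L,
                            match_points = 7L, threshold_at_mean = TRUE) {
  if (levels < match_points || match_points < 1L)
    stop("need levels >= match_points >= 1")
  mv <- as.vector(moving$values)
  if (diff(range(mv)) == 0) {
    warning("constant-valued moving image: histogram matching skipped")
    return(moving)
  }
  # quantiles from a `levels`-bin histogram CDF (linear within bins)
  hist_quantiles <- function(x, probs) {
    r <- range(x)
    if (diff(r) == 0) return(rep(r[1], length(probs)))
    w <- diff(r) / levels
    cnt <- tabulate(pmin(floor((x - r[1]) / w), levels - 1) + 1L,
                    nbins = levels)
    cdf <- c(0, cumsum(cnt)) / length(x)
    vapply(probs, function(p) {
      i <- max(which(cdf <= p + 1e-15)[1], findInterval(p, cdf))
      i <- min(max(i, 1L), levels)
      lo <- cdf[i]; hi <- cdf[i + 1L]
      frac <- if (hi > lo) (p - lo) / (hi - lo) else 0.5
      r[1] + (i - 1L + min(max(frac, 0), 1)) * w
    }, numeric(1))
  }
  fg <- function(x) {
    if (!threshold_at_mean) return(x)
    y <- x[x > mean(x)]
    if (length(y) < match_points + 2L) x else y
  }
  rv <- as.vector(reference$values)
  probs <- seq(0, 1, length.out = match_points + 2L)[-c(1, match_points + 2L)]
  src <- c(min(mv), hist_quantiles(fg(mv), probs), max(mv))
  dst <- c(min(rv), hist_quantiles(fg(rv), probs), max(rv))
  keep <- c(TRUE, diff(src) > 1e-12)
  src <- src[keep]; dst <- dst[keep]
  dst <- cummax(dst)  # monotone non-decreasing map
  if (length(src) < 2L) {
    warning("degenerate moving histogram: matching skipped")
    return(moving)
  }
  out <- stats::approx(src, dst, xout = mv, rule = 2)$y
  scalar_image(array(out, moving$grid$dims), moving$grid)
}

# ---------------------------------------------------------------------------
# Rigid pre-alignment: mean of blockwise normalized cross-correlations,
# optimised by seeded multi-start coordinate descent over 6 parameters.

#' Default settings for [rigid_local_correlation()]
#'
#' @param block_voxels edge length of the cubic correlation blocks (voxels).
#' @param min_block_sd minimum fixed-image intensity SD for a block to be
#'   used (filters structureless air/soft-tissue blocks).
#' @param search_factor images are evaluated on a grid downsampled by this
#'   factor (speed; the transform itself stays continuous).
#' @param rotations if FALSE only the 3 translations are optimised.
#' @param n_starts number of multi-start initial guesses (first is identity).
#' @param max_translation_mm bound for random starts.
#' @param seed RNG seed for the multi-start guesses (determinism).
#' @export
rigid_config <- function(block_voxels = 16L, min_block_sd = 20,
                         search_factor = 2L, rotations = TRUE,
                         n_starts = 4L, max_translation_mm = 15,
                         seed = 0L) {
  list(block_voxels = as.integer(block_voxels), min_block_sd = min_block_sd,
       search_factor = as.integer(search_factor), rotations = rotations,
       n_starts = as.integer(n_starts),
       max_translation_mm = max_translation_mm, seed = as.integer(seed))
}

# mean NCC over precomputed blocks; `blocks` is a list of linear-index
# vectors into the (downsampled) fixed grid
block_ncc <- function(fixed_vals, warped_vals, blocks) {
  s <- vapply(blocks, function(ix) {
    f <- fixed_vals[ix]; m <- warped_vals[ix]
    sf <- stats::sd(f); sm <- stats::sd(m)
    if (sm < 1e-9) return(0)
    mean((f - mean(f)) * (m - mean(m))) / (sf * sm) *
      length(ix) / (length(ix) - 1)
  }, numeric(1))
  mean(s)
}

#' Rigid registration by blockwise local correlation
#'
#' Finds the 6-parameter rigid transform (fixed frame -> moving frame,
#' rotation about the fixed-image centre) maximising the mean of normalized
#' cross-correlations over a cubic block decomposition of the fixed image.
#' Blocks whose fixed-image intensity SD falls below `min_block_sd` are
#' discarded.  Optimisation is derivative-free seeded multi-start
#' coordinate descent with shrinking steps; the accepted-objective trace is
#' returned for audit (non-decreasing by construction).
#'
#' @param fixed,moving `scalar_image`s with overlapping fields of view.
#' @param config settings from [rigid_config()].
#' @return `rigid_transform` with attributes "objective" (final mean NCC)
#'   and "trace" (accepted objective values).
#' @export
rigid_local_correlation <- function(fixed, moving, config = rigid_config()) {
  sf <- max(config$search_factor, 1L)
  fx <- if (sf > 1L) {
    g <- downsample_grid(fixed$grid, sf)
    sm <- smooth_gaussian(fixed$values, 0.5 * sf * fixed$grid$spacing,
                          fixed$grid$spacing)
    resample_to_grid(scalar_image(sm, fixed$grid), g)
  } else fixed
  d <- fx$grid$dims
  b <- max(4L, config$block_voxels %/% sf)
  # block decomposition of the evaluation grid
  bi <- (seq_len(d[1]) - 1L) %/% b
  bj <- (seq_len(d[2]) - 1L) %/% b
  bk <- (seq_len(d[3]) - 1L) %/% b
  block_id <- outer(outer(bi, bj * (max(bi) + 1L), "+"),
                    bk * (max(bi) + 1L) * (max(bj) + 1L), "+")
  fv <- as.vector(fx$values)
  blocks <- split(seq_along(fv), as.vector(block_id))
  usable <- vapply(blocks, function(ix)
    length(ix) >= 8 && stats::sd(fv[ix]) >= config$min_block_sd, logical(1))
  blocks <- blocks[usable]
  if (length(blocks) < 3L) stop("insufficient structure")
  center <- fx$grid$origin + (fx$grid$dims - 1) * fx$grid$spacing / 2
  pts <- grid_points(fx$grid)
  objective <- function(par) {
    tr <- rigid_from_params(par[4:6], par[1:3], center)
    # clamped extrapolation: an air fill would penalise boundary blocks and
    # bias the NCC peak away from the true transform
    w <- trilinear_sample(moving, apply_rigid(tr, pts),
                          extrapolate = "clamp")
    block_ncc(fv, w, blocks)
  }
  n_par <- if (config$rotations) 6L else 3L
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  starts <- list(rep(0, 6))
  if (config$n_starts > 1L) {
    for (s in seq_len(config$n_starts - 1L)) {
      p <- rep(0, 6)
      p[1:3] <- stats::runif(3, -config$max_translation_mm,
                             config$max_translation_mm)
      starts[[s + 1L]] <- p
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  steps_t <- c(8, 4, 2, 1, 0.5, 0.25)   # mm
  steps_r <- c(4, 2, 1, 0.5, 0.25, 0.1) # degrees
  best_par <- NULL; best_obj <- -Inf; best_trace <- NULL
  for (start in starts) {
    par <- start
    obj <- objective(par)
    trace <- obj
    for (lev in seq_along(steps_t)) {
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (p_ in seq_len(n_par)) {
          step <- if (p_ <= 3L) steps_t[lev] else steps_r[lev]
          for (sign_ in c(1, -1)) {
            cand <- par
            cand[p_] <- cand[p_] + sign_ * step
            o <- objective(cand)
            if (o > obj + 1e-10) {
              par <- cand; obj <- o; improved <- TRUE
              trace <- c(trace, obj)
            }
          }
        }
      }
    }
    if (obj > best_obj) { best_obj <- obj; best_par <- par; best_trace <- trace }
  }
  # simplex polish: coordinate descent alone can stall on diagonal ridges
  # where a rotation and a compensating translation must move together
  polish <- stats::optim(best_par[seq_len(n_par)], function(p) {
    pp <- rep(0, 6); pp[seq_len(n_par)] <- p
    -objective(pp)
  }, method = "Nelder-Mead",
  control = list(maxit = 250L, reltol = 1e-9))
  if (-polish$value > best_obj) {
    best_obj <- -polish$value
    best_par[seq_len(n_par)] <- polish$par
    best_trace <- c(best_trace, best_obj)
  }
  out <- rigid_from_params(best_par[4:6], best_par[1:3], center)
  attr(out, "objective") <- best_obj
  attr(out, "trace") <- best_trace
  attr(out, "params") <- best_par
  out
}

#' Resample a moving image through a rigid transform onto a fixed grid
#' @param moving `scalar_image`; `transform` maps fixed points to moving
#'   points; `grid` the fixed grid.
#' @param transform a `rigid_transform`.
#' @param grid target `image_grid`.
#' @export
apply_rigid_to_image <- function(moving, transform, grid) {
  scalar_image(array(trilinear_sample(moving,
                                      apply_rigid(transform, grid_points(grid))),
                     grid$dims), grid)
}
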