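# Salient-feature-based registration (SFBR): automatic interest points
# (scale-normalised Laplacian-of-Gaussian blobs over a dyadic scale
# ladder), descriptor-based mutual-nearest-neighbour matching, and a 3-D
# thin-plate-spline transform interpolating the correspondences.

#' SFBR configuration
#'
#' @param sigma_min_mm finest detection scale (mm).
#' @param n_scales number of half-octave scale steps (sigma_j = sigma_min *
#'   2^(j/2)); a dyadic ladder in sigma^2.
#' @param response_threshold minimum |scale-normalised LoG| response (HU).
#' @param relative_threshold additionally require strength >= this fraction
#'   of the strongest response in the image (suppresses the LoG side-ring
#'   and smoothing/periodicity artifacts).
#' @param nms_spacing_mm minimum spacing between kept features (mm).
#' @param max_features keep at most this many strongest features (default
#'   targets the typical 1000-2000 operating range of feature-based DIR).
#' @param descriptor_radius_factor descriptor neighbourhood radius as a
#'   multiple of the feature scale.
#' @param match_ratio descriptor-distance ratio test (best < ratio * second).
#' @param max_displacement_mm spatial gate on match displacement (post
#'   rigid alignment).
#' @param tps_lambda TPS regularisation (mm); 0 = exact interpolation.
#' @export
sfbr_config <- function(sigma_min_mm = 3, n_scales = 6L,
                        response_threshold = 10,
                        relative_threshold = 0.1, nms_spacing_mm = 6,
                        max_features = 1500L,
                        descriptor_radius_factor = 2,
                        match_ratio = 0.8, max_displacement_mm = 30,
                        tps_lambda = 0.01) {
  structure(list(sigma_min_mm = sigma_min_mm, n_scales = as.integer(n_scales),
                 response_threshold = response_threshold,
                 relative_threshold = relative_threshold,
                 nms_spacing_mm = nms_spacing_mm,
                 max_features = as.integer(max_features),
                 descriptor_radius_factor = descriptor_radius_factor,
                 match_ratio = match_ratio,
                 max_displacement_mm = max_displacement_mm,
                 tps_lambda = tps_lambda),
            class = "sfbr_config")
}

# sigma^3-normalised LoG response (frequency domain); for a 3-D Gaussian
# blob of width sigma_b the response magnitude at the centre peaks at
# sigma_det = sigma_b * sqrt(3/2), so feature scale = sqrt(2) * sigma_det
# equals sigma_b * sqrt(3)
log_response <- function(image, sigma_mm) {
  d <- image$grid$dims
  sp <- image$grid$spacing
  wx <- 2 * pi * fft_freq(d[1], sp[1])
  wy <- 2 * pi * fft_freq(d[2], sp[2])
  wz <- 2 * pi * fft_freq(d[3], sp[3])
  W2 <- outer(outer(wx^2, wy^2, "+"), wz^2, "+")
  H <- -sigma_mm^3 * W2 * exp(-sigma_mm^2 * W2 / 2)
  out <- Re(fft(fft(image$values) * H, inverse = TRUE)) / length(W2)
  dim(out) <- d
  out
}

# 26-neighbourhood (3x3x3) maximum of an array, edge-replicated
neighborhood_max <- function(a) {
  d <- dim(a)
  sh <- function(x, ax, by) {
    n <- d[ax]
    idx <- pmin(pmax(seq_len(n) + by, 1L), n)
    switch(ax, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
           x[, , idx, drop = FALSE])
  }
  m <- a
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    s <- sh(sh(sh(a, 1L, dx), 2L, dy), 3L, dz)
    dim(s) <- d
    m <- pmax(m, s)
  }
  m
}

#' Detect salient features (scale-space LoG blobs)
#'
#' Extrema of the sigma^3-normalised |LoG| over space and a half-octave
#' scale ladder, followed by non-maximum suppression at a minimum spacing
#' and a strongest-N cap.  Each feature carries a position (world mm, voxel
#' resolution), a scale (mm, sqrt(2) x the detection sigma) and a
#' descriptor: an 8-bin normalised local intensity histogram plus the
#' normalised projections of the local mean absolute gradient onto six
#' icosahedral axes, taken in a scale-proportional neighbourhood.
#'
#' @param image a `scalar_image`.
#' @param config an [sfbr_config()].
#' @return data.frame with columns x, y, z (mm), scale (mm), strength,
#'   sign, and a "descriptors" attribute (n x 14 matrix).
#' @export
detect_salient_features <- function(image, config = sfbr_config()) {
  if (diff(range(image$values)) == 0) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      scale = numeric(0), strength = numeric(0),
                      sign = numeric(0))
    attr(out, "descriptors") <- matrix(numeric(0), 0, 14)
    return(out)
  }
  sigmas <- config$sigma_min_mm * 2^((seq_len(config$n_scales) - 1) / 2)
  resp <- lapply(sigmas, function(s) log_response(image, s))
  feats <- list()
  for (j in seq_along(sigmas)) {
    a <- abs(resp[[j]])
    is_max <- a >= neighborhood_max(a) & a > config$response_threshold
    if (j > 1L) is_max <- is_max & a >= abs(resp[[j - 1L]])
    if (j < length(sigmas)) is_max <- is_max & a >= abs(resp[[j + 1L]])
    # exclude extrema closer than the detection sigma to a volume face
    # (the frequency-domain filtering is periodic there)
    g <- image$grid
    margin <- pmax(ceiling(sigmas[j] / g$spacing), 1)
    for (ax in 1:3) {
      n <- g$dims[ax]
      ok <- seq_len(n) > margin[ax] & seq_len(n) <= n - margin[ax]
      if (!any(ok)) ok[] <- FALSE
      if (ax == 1L) is_max[!ok, , ] <- FALSE
      else if (ax == 2L) is_max[, !ok, ] <- FALSE
      else is_max[, , !ok] <- FALSE
    }
    idx <- which(is_max, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    # sub-voxel localisation: 1-D quadratic fit of |response| per axis
    off <- matrix(0, nrow(idx), 3)
    for (ax in 1:3) {
      ip <- idx; ip[, ax] <- pmin(ip[, ax] + 1L, g$dims[ax])
      im <- idx; im[, ax] <- pmax(im[, ax] - 1L, 1L)
      r0 <- a[idx]; rp <- a[ip]; rm <- a[im]
      den <- rm - 2 * r0 + rp
      o <- ifelse(abs(den) > 1e-12, 0.5 * (rm - rp) / den, 0)
      off[, ax] <- pmin(pmax(o, -0.5), 0.5)
    }
    feats[[j]] <- data.frame(
      x = g$origin[1] + (idx[, 1] - 1 + off[, 1]) * g$spacing[1],
      y = g$origin[2] + (idx[, 2] - 1 + off[, 2]) * g$spacing[2],
      z = g$origin[3] + (idx[, 3] - 1 + off[, 3]) * g$spacing[3],
      scale = sqrt(2) * sigmas[j],
      strength = a[idx],
      sign = sign(resp[[j]][idx]))
  }
  f <- do.call(rbind, feats)
  if (is.null(f) || nrow(f) == 0L) {
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      scale = numeric(0), strength = numeric(0),
                      sign = numeric(0))
    attr(out, "descriptors") <- matrix(numeric(0), 0, 14)
    return(out)
  }
  f <- f[f$strength >= config$relative_threshold * max(f$strength), ,
         drop = FALSE]
  f <- f[order(-f$strength), , drop = FALSE]
  # greedy non-maximum suppression at nms_spacing_mm
  keep <- logical(nrow(f))
  kept_xyz <- matrix(0, 0, 3)
  r2 <- config$nms_spacing_mm^2
  for (i in seq_len(nrow(f))) {
    p <- c(f$x[i], f$y[i], f$z[i])
    if (nrow(kept_xyz) == 0L ||
        min((kept_xyz[, 1] - p[1])^2 + (kept_xyz[, 2] - p[2])^2 +
            (kept_xyz[, 3] - p[3])^2) >= r2) {
      keep[i] <- TRUE
      kept_xyz <- rbind(kept_xyz, p)
      if (nrow(kept_xyz) >= config$max_features) break
    }
  }
  f <- f[keep, , drop = FALSE]
  rownames(f) <- NULL
  attr(f, "descriptors") <- feature_descriptors(image, f, config)
  f
}

# 14-dim descriptor per feature: 8-bin intensity histogram (robust range)
# + 6 normalised |gradient| projections on icosahedral axes
feature_descriptors <- function(image, feats, config) {
  n <- nrow(feats)
  desc <- matrix(0, n, 14L)
  if (n == 0L) return(desc)
  g <- image$grid
  gr <- gradient_mm(image$values, g$spacing)
  axes <- quadrature_filter_bank()$directions
  for (i in seq_len(n)) {
    r <- config$descriptor_radius_factor * feats$scale[i]
    ctr <- c(feats$x[i], feats$y[i], feats$z[i])
    lo <- pmax(floor((ctr - r - g$origin) / g$spacing) + 1, 1)
    hi <- pmin(ceiling((ctr + r - g$origin) / g$spacing) + 1, g$dims)
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    px <- g$origin[1] + (ix - 1) * g$spacing[1]
    py <- g$origin[2] + (iy - 1) * g$spacing[2]
    pz <- g$origin[3] + (iz - 1) * g$spacing[3]
    inside <- outer(outer((px - ctr[1])^2, (py - ctr[2])^2, "+"),
                    (pz - ctr[3])^2, "+") <= r^2
    vals <- image$values[ix, iy, iz][inside]
    q <- stats::quantile(vals, c(0.05, 0.95), names = FALSE)
    if (q[2] - q[1] < 1e-9) q <- q + c(-0.5, 0.5)
    h <- tabulate(pmin(pmax(ceiling((vals - q[1]) / (q[2] - q[1]) * 8), 1), 8),
                  nbins = 8L)
    desc[i, 1:8] <- h / sum(h)
    gm <- cbind(abs(gr[[1]][ix, iy, iz][inside]),
                abs(gr[[2]][ix, iy, iz][inside]),
                abs(gr[[3]][ix, iy, iz][inside]))
    proj <- colMeans(gm %*% t(abs(axes)))
    nrm <- sqrt(sum(proj^2))
    desc[i, 9:14] <- if (nrm > 1e-12) proj / nrm else 0
  }
  desc
}

#' Match features between two images
#'
#' Mutual-nearest-neighbour matching on Euclidean descriptor distance,
#' gated by a maximum spatial displacement and Lowe's ratio test
#' (best < ratio * second-best).  One-to-one correspondences.
#'
#' @param fixed_feats,moving_feats feature tables from
#'   [detect_salient_features()] (non-empty).
#' @param config an [sfbr_config()].
#' @return data.frame of correspondences: fixed x/y/z, moving x/y/z,
#'   descriptor distance.
#' @export
match_features <- function(fixed_feats, moving_feats,
                           config = sfbr_config()) {
  if (nrow(fixed_feats) == 0L || nrow(moving_feats) == 0L)
    stop("feature lists must be non-empty")
  df <- attr(fixed_feats, "descriptors")
  dm <- attr(moving_feats, "descriptors")
  pf <- as.matrix(fixed_feats[, c("x", "y", "z")])
  pm <- as.matrix(moving_feats[, c("x", "y", "z")])
  # descriptor distance matrix (fixed x moving)
  d2 <- outer(rowSums(df^2), rowSums(dm^2), "+") - 2 * df %*% t(dm)
  d2[d2 < 0] <- 0
  # spatial gate
  gate2 <- config$max_displacement_mm^2
  s2 <- outer(rowSums(pf^2), rowSums(pm^2), "+") - 2 * pf %*% t(pm)
  d2[s2 > gate2] <- Inf
  best_m <- apply(d2, 1, which.min)
  best_d <- d2[cbind(seq_len(nrow(d2)), best_m)]
  second <- apply(d2, 1, function(r) sort(r, partial = 2)[2])
  best_f_of_m <- apply(d2, 2, which.min)
  # ratio gate: a feature with no in-gate second neighbour passes for any
  # positive ratio (Lowe's convention) and fails for ratio = 0
  rhs <- config$match_ratio * sqrt(second)
  rhs[!is.finite(second)] <- if (config$match_ratio > 0) Inf else 0
  ok <- is.finite(best_d) &
    best_f_of_m[best_m] == seq_len(nrow(d2)) &            # mutual NN
    sqrt(best_d) < rhs                                    # ratio test
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) stop("no correspondences")
  data.frame(fx = pf[ok, 1], fy = pf[ok, 2], fz = pf[ok, 3],
             mx = pm[best_m[ok], 1], my = pm[best_m[ok], 2],
             mz = pm[best_m[ok], 3],
             desc_dist = sqrt(best_d[ok]))
}

# ---------------------------------------------------------------------------
# Thin-plate splines (3-D biharmonic kernel U(r) = r)

#' Fit a 3-D thin-plate-spline transform to correspondences
#'
#' Solves the standard bordered linear system for the kernel
#' U(r) = r (the 3-D biharmonic spline); `lambda` = 0 gives exact
#' interpolation at the landmarks.  The side conditions (kernel weights sum
#' to zero and are first-moment free) hold by construction.
#'
#' @param source n x 3 matrix of source-frame landmarks (mm).
#' @param target n x 3 matrix of corresponding target-frame points (mm).
#' @param lambda regularisation (mm) added to the kernel diagonal.
#' @param direction which way the map goes, "fixed_to_moving" (pull-back,
#'   used to build displacement fields) or "moving_to_fixed" (used to
#'   propagate pre-treatment meshes forward).
#' @return object of class `tps_transform`: landmarks, 3 x 4 affine part,
#'   n x 3 kernel weights, lambda, direction; attribute "rcond" carries the
#'   reciprocal condition number of the bordered system.
#' @export
fit_tps <- function(source, target, lambda = 0,
                    direction = c("fixed_to_moving", "moving_to_fixed")) {
  direction <- match.arg(direction)
  source <- as.matrix(source); target <- as.matrix(target)
  n <- nrow(source)
  if (n < 5L || nrow(target) != n) stop("need >= 5 correspondences")
  if (lambda < 0) stop("lambda must be >= 0")
  sv <- svd(sweep(source, 2, colMeans(source)))$d
  if (sv[3] < 1e-8 * sv[1])
    stop("degenerate landmark set: source points are coplanar or collinear")
  K <- as.matrix(stats::dist(source, diag = TRUE, upper = TRUE))
  P <- cbind(1, source)
  # U(r) = r is conditionally negative definite, so the spline ridge is
  # K - lambda I (adding +lambda I would move the system towards
  # singularity instead of away from it)
  L <- rbind(cbind(K - diag(lambda, n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(target, matrix(0, 4, 3))
  sol <- solve(L, rhs)
  rc <- if (n <= 600L) rcond(L) else NA_real_
  structure(list(source_landmarks = source, target_landmarks = target,
                 weights = sol[seq_len(n), , drop = FALSE],
                 affine = t(sol[n + 1:4, , drop = FALSE]),  # 3 x 4: [b | A]
                 lambda = lambda, direction = direction),
            class = "tps_transform", rcond = rc)
}

#' Evaluate a thin-plate-spline transform at points
#'
#' f(x) = b + A x + sum_i w_i |x - x_i|, vectorised and chunked over
#' points.
#' @param tps a `tps_transform`.
#' @param points n x 3 matrix of source-frame points (mm).
#' @return n x 3 matrix of mapped points (mm).
#' @export
evaluate_tps <- function(tps, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  out <- matrix(0, nrow(points), 3)
  X <- tps$source_landmarks
  W <- tps$weights
  A <- tps$affine
  xl2 <- rowSums(X^2)
  chunk <- 4000L
  for (i0 in seq(1L, nrow(points), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(points))
    p <- points[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(p^2), xl2, "+") - 2 * p %*% t(X)
    d2[d2 < 0] <- 0
    out[i0:i1, ] <- sweep(p %*% t(A[, 2:4]), 2, A[, 1], "+") + sqrt(d2) %*% W
  }
  out
}

#' TPS bending energy
#'
#' -sum_c w_c' K w_c with K the kernel matrix; non-negative under the
#' moment side-conditions (U(r) = r is conditionally negative definite),
#' and zero iff the map is affine.
#' @param tps a `tps_transform`.
#' @export
tps_bending_energy <- function(tps) {
  K <- as.matrix(stats::dist(tps$source_landmarks, diag = TRUE, upper = TRUE))
  -sum(vapply(1:3, function(c_)
    drop(crossprod(tps$weights[, c_], K %*% tps$weights[, c_])), numeric(1)))
}

#' Convert a fixed-to-moving TPS into a displacement field on a grid
#' @param tps a `tps_transform` with direction "fixed_to_moving".
#' @param grid the fixed `image_grid`.
#' @export
tps_to_field <- function(tps, grid) {
  if (tps$direction != "fixed_to_moving")
    stop("field conversion needs a fixed_to_moving TPS")
  pts <- grid_points(grid)
  displacement_field(array(evaluate_tps(tps, pts) - pts, c(grid$dims, 3L)),
                     grid)
}

#' Salient-feature-based registration
#'
#' Detects features in both images, matches them, and fits two TPS
#' transforms: the pull-back map (fixed -> moving, from which a
#' displacement field can be sampled) and the forward map (moving ->
#' fixed, used to propagate pre-treatment meshes).
#'
#' @param fixed,moving `scalar_image`s (rigidly pre-aligned).
#' @param config an [sfbr_config()].
#' @return list(tps_pullback, tps_forward, matches, n_fixed_features,
#'   n_moving_features).
#' @export
sfbr_register <- function(fixed, moving, config = sfbr_config()) {
  ff <- detect_salient_features(fixed, config)
  mf <- detect_salient_features(moving, config)
  matches <- match_features(ff, mf, config)
  src_f <- as.matrix(matches[, c("fx", "fy", "fz")])
  src_m <- as.matrix(matches[, c("mx", "my", "mz")])
  list(tps_pullback = fit_tps(src_f, src_m, config$tps_lambda,
                              "fixed_to_moving"),
       tps_forward = fit_tps(src_m, src_f, config$tps_lambda,
                             "moving_to_fixed"),
       matches = matches,
       n_fixed_features = nrow(ff), n_moving_features = nrow(mf))
}
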