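# Core geometric data model: regular 3-D grids, scalar images, displacement
# fields, rigid transforms, binary ROI masks and triangle meshes.
#
# Conventions (used everywhere in the package):
#   * voxel indices are 0-based; world coordinate of voxel (i,j,k) is
#     origin + index * spacing (mm); axis 3 is the axial (slice) axis;
#   * arrays are stored in R's column-major order, first index fastest;
#   * displacement fields live on the FIXED image grid in the pull-back
#     convention: the vector u(x) at fixed voxel centre x points to the
#     corresponding location x + u(x) in the moving image.

#' Regular 3-D image grid
#'
#' @param dims integer triple (nx, ny, nz), all >= 1.
#' @param spacing positive mm triple (in-plane x, in-plane y, slice).
#' @param origin world-mm coordinate of voxel (0, 0, 0). Default c(0, 0, 0).
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(dims, spacing, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || any(dims < 1L) || anyNA(dims))
    stop("dims must be 3 integers >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite numbers (mm)")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %d x %d x %d voxels, spacing %g x %g x %g mm, origin (%g, %g, %g)\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$dims)

grids_equal <- function(a, b, tol = 1e-9) {
  all(a$dims == b$dims) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' World-mm coordinates of all voxel centres
#'
#' @param grid an `image_grid`.
#' @return n_voxels x 3 matrix in array (column-major) order.
#' @export
grid_points <- function(grid) {
  d <- grid$dims
  i <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  cbind(grid$origin[1] + i * grid$spacing[1],
        grid$origin[2] + j * grid$spacing[2],
        grid$origin[3] + k * grid$spacing[3])
}

#' Scalar image on a regular grid
#'
#' @param values numeric array with dim equal to `grid$dims` (HU for CT).
#' @param grid an `image_grid`.
#' @return Object of class `scalar_image` with fields `values` and `grid`.
#' @export
scalar_image <- function(values, grid) {
  values <- as.array(values)
  if (length(values) != n_voxels(grid))
    stop("value count does not match grid dims")
  if (!all(is.finite(values))) stop("image values must be finite")
  dim(values) <- grid$dims
  structure(list(values = values, grid = grid), class = "scalar_image")
}

#' @export
print.scalar_image <- function(x, ...) {
  cat("scalar_image\n  ")
  print(x$grid)
  cat(sprintf("  intensity range [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Displacement field (fixed-frame, pull-back convention)
#'
#' @param vectors numeric array of dim c(grid$dims, 3): per-voxel world-mm
#'   displacement components. `vectors[i,j,k,]` points from fixed voxel
#'   centre x to the matched moving-image location x + u(x).
#' @param grid the fixed image's `image_grid`.
#' @return Object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, grid) {
  vectors <- as.array(vectors)
  if (length(vectors) != 3L * n_voxels(grid))
    stop("vector count does not match grid dims")
  if (!all(is.finite(vectors))) stop("field components must be finite")
  dim(vectors) <- c(grid$dims, 3L)
  structure(list(vectors = vectors, grid = grid), class = "displacement_field")
}

#' Zero displacement field on a grid
#' @param grid an `image_grid`.
#' @export
zero_field <- function(grid) {
  displacement_field(array(0, c(grid$dims, 3L)), grid)
}

field_matrix <- function(dvf) {
  m <- dvf$vectors
  dim(m) <- c(n_voxels(dvf$grid), 3L)
  m
}

#' @export
print.displacement_field <- function(x, ...) {
  m <- field_matrix(x)
  mag <- sqrt(rowSums(m^2))
  cat("displacement_field (pull-back, fixed frame)\n  ")
  print(x$grid)
  cat(sprintf("  |u|: mean %.3f mm, max %.3f mm\n", mean(mag), max(mag)))
  invisible(x)
}

#' Rigid transform (rotation + translation, world mm)
#'
#' Maps fixed-frame points to moving-frame points: y = R x + t.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation mm 3-vector.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation determinant must be +1")
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("translation must be a finite 3-vector")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix of world-mm points.
#' @export
apply_rigid <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Rigid transform from Euler angles about the image centre
#'
#' Angles are applied as Rz(rz) Ry(ry) Rx(rx) about `center`; the rotation
#' centre is folded into the stored translation.
#'
#' @param angles_deg rotation angles (degrees) about x, y, z world axes.
#' @param translation_mm mm 3-vector added after rotation.
#' @param center world-mm rotation centre.
#' @export
rigid_from_params <- function(angles_deg = c(0, 0, 0),
                              translation_mm = c(0, 0, 0),
                              center = c(0, 0, 0)) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  R <- Rz %*% Ry %*% Rx
  t <- as.numeric(center - R %*% center + translation_mm)
  rigid_transform(R, t)
}

#' Binary ROI mask
#'
#' @param labels array of 0/1 (or logical) with dim `grid$dims`.
#' @param grid an `image_grid`.
#' @param name ROI identifier, e.g. "GTV", "lung-L", "cord".
#' @export
roi_mask <- function(labels, grid, name = "ROI") {
  labels <- as.array(labels)
  if (is.logical(labels)) labels <- labels + 0L
  if (length(labels) != n_voxels(grid))
    stop("label count does not match grid dims")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  storage.mode(labels) <- "integer"
  dim(labels) <- grid$dims
  structure(list(labels = labels, grid = grid, name = as.character(name)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask '%s': %d voxels (%.2f cm^3)\n  ", x$name,
              sum(x$labels), mask_volume_cm3(x)))
  print(x$grid)
  invisible(x)
}

#' Mask volume in cm^3 (voxel count times voxel volume)
#' @param mask a `roi_mask`.
#' @export
mask_volume_cm3 <- function(mask) {
  sum(mask$labels) * prod(mask$grid$spacing) / 1000
}

#' Closed triangle mesh in world mm
#'
#' @param vertices n x 3 matrix of world-mm points.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param frame which image frame the vertices live in ("moving" for
#'   pre-treatment ROIs, "fixed" for mid-treatment).
#' @export
contour_mesh <- function(vertices, faces, frame = c("moving", "fixed")) {
  frame <- match.arg(frame)
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (ncol(vertices) != 3L || !all(is.finite(vertices)))
    stop("vertices must be a finite n x 3 matrix")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces, frame = frame),
            class = "contour_mesh")
}

#' @export
print.contour_mesh <- function(x, ...) {
  cat(sprintf("contour_mesh (%s frame): %d vertices, %d faces\n",
              x$frame, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Check that every mesh edge is shared by exactly two faces
#' @param mesh a `contour_mesh`.
#' @return logical.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Signed volume enclosed by a closed mesh (mm^3)
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for
#' outward-oriented faces.
#' @param mesh a `contour_mesh`.
#' @export
mesh_volume_mm3 <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                 b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                 b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cross)) / 6
}

# ---------------------------------------------------------------------------
# Interpolation and warping

# points (world mm) -> continuous 0-based voxel index
continuous_index <- function(grid, points) {
  sweep(sweep(points, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

#' Trilinear interpolation of a scalar image at world-mm points
#'
#' Points outside the grid return `fill` (default: the minimum image value,
#' an air-like fill for CT) unless `extrapolate = "clamp"`, which clamps the
#' continuous index to the grid edge (used for resampling vector fields,
#' where an air fill would be meaningless).
#'
#' @param image a `scalar_image`.
#' @param points n x 3 matrix (or length-3 vector) of world-mm points.
#' @param fill value returned outside the grid; default min(image).
#' @param extrapolate "fill" (default) or "clamp".
#' @return numeric vector of n interpolated values.
#' @export
trilinear_sample <- function(image, points, fill = NULL,
                             extrapolate = c("fill", "clamp")) {
  extrapolate <- match.arg(extrapolate)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (!all(is.finite(points))) stop("non-finite sample point")
  g <- image$grid
  d <- g$dims
  ci <- continuous_index(g, points)
  outside <- ci[, 1] < 0 | ci[, 1] > d[1] - 1 |
             ci[, 2] < 0 | ci[, 2] > d[2] - 1 |
             ci[, 3] < 0 | ci[, 3] > d[3] - 1
  if (extrapolate == "clamp") {
    for (ax in 1:3) ci[, ax] <- pmin(pmax(ci[, ax], 0), d[ax] - 1)
    outside[] <- FALSE
  }
  i0 <- floor(ci)
  # keep the upper cell corner in range (points exactly on the last plane)
  for (ax in 1:3) i0[, ax] <- pmin(pmax(i0[, ax], 0), max(d[ax] - 2, 0))
  fr <- ci - i0
  for (ax in 1:3) if (d[ax] == 1L) fr[, ax] <- 0
  v <- image$values
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- 1 + i0[, 1] + n1 * i0[, 2] + n12 * i0[, 3]
  s1 <- if (d[1] > 1L) 1 else 0
  s2 <- if (d[2] > 1L) n1 else 0
  s3 <- if (d[3] > 1L) n12 else 0
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  c00 <- v[base]           * (1 - fx) + v[base + s1]           * fx
  c10 <- v[base + s2]      * (1 - fx) + v[base + s1 + s2]      * fx
  c01 <- v[base + s3]      * (1 - fx) + v[base + s1 + s3]      * fx
  c11 <- v[base + s2 + s3] * (1 - fx) + v[base + s1 + s2 + s3] * fx
  out <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
         (c01 * (1 - fy) + c11 * fy) * fz
  if (any(outside)) {
    if (is.null(fill)) fill <- min(v)
    out[outside] <- fill
  }
  out
}

#' Warp a moving image through a pull-back displacement field
#'
#' The output lives on the field's (fixed) grid: out(x) =
#' moving(x + u(x)), sampled trilinearly.
#'
#' @param moving a `scalar_image` (pre-treatment frame).
#' @param dvf a `displacement_field` on the fixed grid.
#' @param fill out-of-grid fill value, default min(moving).
#' @param extrapolate "fill" (default) or "clamp"; registration internals
#'   use "clamp" so anatomy cut at the volume edge does not generate
#'   spurious air-fill mismatch forces.
#' @return `scalar_image` on `dvf$grid`.
#' @export
warp_pullback <- function(moving, dvf, fill = NULL,
                          extrapolate = c("fill", "clamp")) {
  pts <- grid_points(dvf$grid) + field_matrix(dvf)
  scalar_image(array(trilinear_sample(moving, pts, fill = fill,
                                      extrapolate = match.arg(extrapolate)),
                     dvf$grid$dims), dvf$grid)
}

#' Resample a scalar image onto a different grid (trilinear)
#' @param image a `scalar_image`.
#' @param grid target `image_grid`.
#' @param fill out-of-grid fill value, default min(image).
#' @export
resample_to_grid <- function(image, grid, fill = NULL) {
  if (n_voxels(grid) < 1L) stop("empty target grid")
  if (grids_equal(image$grid, grid)) {
    return(scalar_image(image$values, grid))
  }
  scalar_image(array(trilinear_sample(image, grid_points(grid), fill = fill),
                     grid$dims), grid)
}

# Coarse grid for integer downsampling factor: same origin (voxel centres of
# the coarse grid coincide with every factor-th fine centre), spacing scaled.
downsample_grid <- function(grid, factor) {
  image_grid(dims = pmax(ceiling(grid$dims / factor), 1L),
             spacing = grid$spacing * factor,
             origin = grid$origin)
}

#' Resample a displacement field onto a grid
#'
#' Vectors are interpolated componentwise with clamped-edge extrapolation;
#' components remain world mm, so their physical magnitude is preserved
#' across resolutions.
#' @param dvf a `displacement_field`.
#' @param grid target `image_grid`.
#' @export
resample_field <- function(dvf, grid) {
  if (n_voxels(grid) < 1L) stop("empty target grid")
  pts <- grid_points(grid)
  out <- array(0, c(grid$dims, 3L))
  for (c_ in 1:3) {
    comp <- scalar_image(dvf$vectors[, , , c_], dvf$grid)
    out[, , , c_] <- trilinear_sample(comp, pts, extrapolate = "clamp")
  }
  displacement_field(out, grid)
}

#' Downsample / upsample a displacement field by an integer factor
#' @param dvf a `displacement_field`.
#' @param factor integer >= 1.
#' @rdname resample_field
#' @export
downsample_field <- function(dvf, factor) {
  if (factor < 1) stop("factor must be >= 1")
  resample_field(dvf, downsample_grid(dvf$grid, factor))
}

#' @rdname resample_field
#' @export
upsample_field <- function(dvf, factor) {
  if (factor < 1) stop("factor must be >= 1")
  g <- dvf$grid
  fine <- image_grid(dims = g$dims * as.integer(factor),
                     spacing = g$spacing / factor,
                     origin = g$origin)
  resample_field(dvf, fine)
}

# ---------------------------------------------------------------------------
# Gradients, smoothing, Jacobians

# Per-axis partial derivatives of a 3-D array in value-units per mm
# (central differences inside, one-sided at the faces). Returns a list of
# three arrays.
gradient_mm <- function(arr, spacing) {
  d <- dim(arr)
  out <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    if (n == 1L) { out[[ax]] <- array(0, d); next }
    idx_p <- pmin(seq_len(n) + 1L, n)
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    step <- (idx_p - idx_m) * spacing[ax]
    if (ax == 1L) {
      g <- (arr[idx_p, , , drop = FALSE] - arr[idx_m, , , drop = FALSE]) /
        step
    } else if (ax == 2L) {
      g <- sweep(arr[, idx_p, , drop = FALSE] - arr[, idx_m, , drop = FALSE],
                 2, step, "/")
    } else {
      g <- sweep(arr[, , idx_p, drop = FALSE] - arr[, , idx_m, drop = FALSE],
                 3, step, "/")
    }
    dim(g) <- d
    out[[ax]] <- g
  }
  out
}

# frequencies (cycles per mm) of an n-point DFT with sample spacing `sp`
fft_freq <- function(n, sp) {
  k <- c(seq.int(0L, floor(n / 2)), seq.int(-(ceiling(n / 2) - 1L), -1L))
  if (n == 1L) k <- 0L
  k / (n * sp)
}

#' Gaussian smoothing of a 3-D array (frequency-domain, per-axis sigma in mm)
#'
#' Implemented as multiplication with the continuous Gaussian transfer
#' function exp(-2 pi^2 sigma^2 f^2) in the DFT domain; boundary handling is
#' therefore circular.  sigma = 0 on an axis leaves that axis untouched.
#'
#' @param arr numeric 3-D array.
#' @param sigma_mm scalar or length-3 smoothing sigma (mm).
#' @param spacing grid spacing (mm triple).
#' @return smoothed array of the same dim.
#' @export
smooth_gaussian <- function(arr, sigma_mm, spacing) {
  sigma <- rep_len(as.numeric(sigma_mm), 3L)
  if (all(sigma <= 0)) return(arr)
  d <- dim(arr)
  H <- 1
  hx <- exp(-2 * pi^2 * sigma[1]^2 * fft_freq(d[1], spacing[1])^2)
  hy <- exp(-2 * pi^2 * sigma[2]^2 * fft_freq(d[2], spacing[2])^2)
  hz <- exp(-2 * pi^2 * sigma[3]^2 * fft_freq(d[3], spacing[3])^2)
  H <- outer(outer(hx, hy), hz)
  out <- Re(fft(fft(arr) * H, inverse = TRUE)) / length(arr)
  dim(out) <- d
  out
}

# smooth each component of a field
smooth_field <- function(dvf, sigma_mm) {
  v <- dvf$vectors
  for (c_ in 1:3)
    v[, , , c_] <- smooth_gaussian(dvf$vectors[, , , c_], sigma_mm,
                                   dvf$grid$spacing)
  displacement_field(v, dvf$grid)
}

#' Gradient magnitude of a scalar image (value units per mm)
#'
#' Central-difference gradient magnitude; used e.g. to delimit
#' "high-gradient" regions (organ boundaries) when assessing registration
#' endpoint error.
#' @param image a `scalar_image`.
#' @return array of per-voxel gradient magnitudes.
#' @export
gradient_magnitude <- function(image) {
  g <- gradient_mm(image$values, image$grid$spacing)
  sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
}

#' Jacobian determinant of the mapping x -> x + u(x)
#'
#' Computed with central finite differences of the field; values <= 0
#' indicate folding of the deformation.
#' @param dvf a `displacement_field`.
#' @return array of per-voxel determinants.
#' @export
jacobian_determinant <- function(dvf) {
  g <- dvf$grid
  J <- array(0, c(g$dims, 3L, 3L))
  for (c_ in 1:3) {
    gr <- gradient_mm(dvf$vectors[, , , c_], g$spacing)
    for (ax in 1:3) J[, , , c_, ax] <- gr[[ax]]
    J[, , , c_, c_] <- J[, , , c_, c_] + 1
  }
  J[, , , 1, 1] * (J[, , , 2, 2] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 2]) -
  J[, , , 1, 2] * (J[, , , 2, 1] * J[, , , 3, 3] - J[, , , 2, 3] * J[, , , 3, 1]) +
  J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] - J[, , , 2, 2] * J[, , , 3, 1])
}
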