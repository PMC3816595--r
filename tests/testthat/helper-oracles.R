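# Shared fixtures and independent brute-force oracles used across the
# suite.  Oracles are deliberately written as plain nested loops, separate
# from the vectorised implementation paths they check.

# small random image on an anisotropic grid
tiny_image <- function(dims = c(5, 5, 5), spacing = c(2, 2, 3), seed = 1) {
  g <- image_grid(dims, spacing)
  set.seed(seed)
  scalar_image(array(rnorm(prod(dims), 0, 100), dims), g)
}

# nested-loop trilinear interpolation at a single point (0-based index math
# written out longhand)
oracle_trilinear <- function(image, pt, fill = min(image$values)) {
  g <- image$grid
  ci <- (pt - g$origin) / g$spacing
  d <- g$dims
  if (any(ci < 0) || any(ci > d - 1)) return(fill)
  i0 <- pmin(pmax(floor(ci), 0), pmax(d - 2, 0))
  fr <- ci - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- pmin(i0 + c(dx, dy, dz), d - 1)
    w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
    acc <- acc + w * image$values[ii[1] + 1, ii[2] + 1, ii[3] + 1]
  }
  acc
}

# exhaustive per-slice symmetric Hausdorff between boundary point sets
oracle_mshd <- function(a, b) {
  vals <- c()
  for (k in seq_len(a$grid$dims[3])) {
    pa <- dirprop:::slice_boundary_points(a, k)
    pb <- dirprop:::slice_boundary_points(b, k)
    if (is.null(pa) || is.null(pb)) next
    dmax <- 0
    for (i in seq_len(nrow(pa))) {
      dmin <- Inf
      for (j in seq_len(nrow(pb)))
        dmin <- min(dmin, sqrt(sum((pa[i, ] - pb[j, ])^2)))
      dmax <- max(dmax, dmin)
    }
    for (j in seq_len(nrow(pb))) {
      dmin <- Inf
      for (i in seq_len(nrow(pa)))
        dmin <- min(dmin, sqrt(sum((pb[j, ] - pa[i, ])^2)))
      dmax <- max(dmax, dmin)
    }
    vals <- c(vals, dmax)
  }
  mean(vals)
}

# random small blob mask: a couple of overlapping spheres
random_blob_mask <- function(grid, seed, name = "blob") {
  set.seed(seed)
  pts <- grid_points(grid)
  ext <- (grid$dims - 1) * grid$spacing
  lab <- rep(FALSE, nrow(pts))
  for (s in seq_len(sample(1:2, 1))) {
    ctr <- grid$origin + runif(3, 0.25, 0.75) * ext
    r <- runif(1, 0.15, 0.3) * min(ext)
    lab <- lab | (rowSums(sweep(pts, 2, ctr)^2) <= r^2)
  }
  if (!any(lab)) lab[sample(length(lab), 3)] <- TRUE
  roi_mask(array(as.integer(lab), grid$dims), grid, name)
}

# small thorax-like phantom spec scaled onto a coarse grid (fast tests)
small_phantom_spec <- function(noise = 10, seed = 0)
  phantom_spec(grid = image_grid(c(64, 64, 24), c(4, 4, 6)),
               noise_sigma_hu = noise, seed = seed)

small_bump <- function(amp = c(4, -2, 4))
  gt_deformation("gaussian_bump", amplitude_mm = amp,
                 center = c(172, 115, 72), sigma_mm = 30)

# reduced demons schedule matched to the small phantom
small_demons_config <- function(...)
  demons_config(schedule = pyramid_schedule(c(4L, 2L, 1L),
                                            c(100L, 60L, 30L),
                                            c(3, 3, 1.5)), ...)
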