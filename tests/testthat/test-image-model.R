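test_that("constructors validate their invariants", {
  expect_error(image_grid(c(0, 4, 4), c(1, 1, 1)), "dims")
  expect_error(image_grid(c(4, 4, 4), c(1, -1, 1)), "spacing")
  g <- image_grid(c(4, 4, 4), c(1, 1, 1))
  expect_error(scalar_image(array(0, c(4, 4, 3)), g), "count")
  expect_error(scalar_image(array(NA_real_, c(4, 4, 4)), g), "finite")
  expect_error(roi_mask(array(2L, c(4, 4, 4)), g), "binary")
  expect_error(displacement_field(array(Inf, c(4, 4, 4, 3)), g), "finite")
  expect_error(rigid_transform(diag(3) * 2, c(0, 0, 0)), "orthonormal")
  # reflections (determinant -1) rejected
  expect_error(rigid_transform(diag(c(-1, 1, 1)), c(0, 0, 0)), "determinant")
})

test_that("world coordinates follow origin + index * spacing", {
  g <- image_grid(c(3, 2, 2), c(2, 2, 3), origin = c(10, -5, 0))
  p <- grid_points(g)
  expect_equal(p[1, ], c(10, -5, 0))
  expect_equal(p[2, ], c(12, -5, 0))          # +x fastest
  expect_equal(p[nrow(p), ], c(14, -3, 3))
})

test_that("trilinear sampling: identity at centres, linear at midpoints", {
  img <- tiny_image()
  p <- grid_points(img$grid)
  expect_equal(trilinear_sample(img, p), as.vector(img$values),
               tolerance = 1e-12)
  # midpoint between two voxels valued 0 and 100
  g <- image_grid(c(2, 1, 1), c(4, 1, 1))
  two <- scalar_image(array(c(0, 100), c(2, 1, 1)), g)
  expect_equal(trilinear_sample(two, c(2, 0, 0)), 50)
  expect_error(trilinear_sample(two, c(NaN, 0, 0)), "finite")
})

test_that("trilinear sampling equals the nested-loop oracle", {
  img <- tiny_image(seed = 3)
  set.seed(11)
  ext <- (img$grid$dims - 1) * img$grid$spacing
  pts <- sweep(matrix(runif(30, -0.1, 1.1), 10, 3), 2, ext, "*")
  got <- trilinear_sample(img, pts)
  want <- vapply(seq_len(10), function(i) oracle_trilinear(img, pts[i, ]),
                 numeric(1))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("out-of-grid sampling fills with the image minimum by default", {
  img <- tiny_image()
  far <- c(-100, -100, -100)
  expect_equal(trilinear_sample(img, far), min(img$values))
  expect_equal(trilinear_sample(img, far, fill = -5), -5)
  # clamped extrapolation returns the nearest edge value instead
  expect_equal(trilinear_sample(img, c(-100, 0, 0), extrapolate = "clamp"),
               img$values[1, 1, 1])
})

test_that("warp_pullback: zero field is the identity, constant field shifts", {
  img <- tiny_image(dims = c(8, 8, 8), seed = 5)
  g <- img$grid
  expect_equal(warp_pullback(img, zero_field(g))$values, img$values)
  v <- array(0, c(g$dims, 3)); v[, , , 1] <- g$spacing[1]
  w <- warp_pullback(img, displacement_field(v, g))
  expect_equal(w$values[1:7, , ], img$values[2:8, , ], tolerance = 1e-12)
})

test_that("warp_pullback equals the per-voxel oracle on a smooth field", {
  img <- tiny_image(dims = c(8, 8, 8), spacing = c(2, 2, 3), seed = 7)
  g <- img$grid
  p <- grid_points(g)
  u <- cbind(1.5 * sin(p[, 2] / 8), 1.2 * cos(p[, 1] / 9),
             0.8 * sin(p[, 3] / 7))
  dvf <- displacement_field(array(u, c(g$dims, 3)), g)
  got <- warp_pullback(img, dvf)$values
  want <- array(0, g$dims)
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    lin <- i + 8 * (j - 1) + 64 * (k - 1)
    want[i, j, k] <- oracle_trilinear(img, p[lin, ] + u[lin, ])
  }
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("warping with u then -u approximately recovers a smooth image", {
  g <- image_grid(c(24, 24, 16), c(2, 2, 3))
  p <- grid_points(g)
  img <- scalar_image(array(100 * sin(p[, 1] / 10) * cos(p[, 2] / 12) +
                            50 * sin(p[, 3] / 9), g$dims), g)
  u <- cbind(2 * exp(-((p[, 1] - 24)^2 + (p[, 2] - 24)^2) / 400),
             -1.5 * exp(-((p[, 2] - 20)^2 + (p[, 3] - 20)^2) / 300),
             rep(0.5, nrow(p)))
  fwd <- displacement_field(array(u, c(g$dims, 3)), g)
  bwd <- displacement_field(array(-u, c(g$dims, 3)), g)
  rec <- warp_pullback(warp_pullback(img, fwd, extrapolate = "clamp"), bwd,
                       extrapolate = "clamp")
  # error bounded by |grad image| x |u| (loose empirical factor)
  gbound <- max(gradient_magnitude(img)) * max(sqrt(rowSums(u^2)))
  expect_lt(sqrt(mean((rec$values - img$values)^2)), gbound)
  expect_lt(sqrt(mean((rec$values - img$values)^2)),
            0.2 * sqrt(mean(img$values^2)))
})

test_that("resampling: identity grid is bitwise, fields keep mm vectors", {
  img <- tiny_image(dims = c(8, 8, 8))
  expect_identical(resample_to_grid(img, img$grid)$values, img$values)
  expect_error(resample_to_grid(img, image_grid(c(1, 1, 1), c(1, 1, 1),
                                                c(1e6, 0, 0))), NA)
  g <- img$grid
  const <- displacement_field(array(rep(c(1.5, -2, 3),
                                        each = prod(g$dims)),
                                    c(g$dims, 3)), g)
  up <- upsample_field(const, 2)
  expect_equal(dim(up$vectors)[1:3], g$dims * 2L)
  expect_true(all(abs(up$vectors[, , , 1] - 1.5) < 1e-12))
  expect_true(all(abs(up$vectors[, , , 3] - 3) < 1e-12))
  expect_equal(up$grid$spacing, g$spacing / 2)
})

test_that("down-then-upsampling a smooth low-frequency field is faithful", {
  g <- image_grid(c(32, 32, 16), c(2, 2, 3))
  p <- grid_points(g)
  u <- cbind(3 * sin(p[, 1] / 20) * cos(p[, 2] / 25),
             2 * cos(p[, 3] / 15), 1.5 * sin(p[, 2] / 30))
  dvf <- displacement_field(array(u, c(g$dims, 3)), g)
  rt <- resample_field(downsample_field(dvf, 2), g)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(rt$vectors - dvf$vectors), 0.05 * rms(dvf$vectors))
})

test_that("smooth_gaussian: sigma 0 is identity, huge sigma gives the mean", {
  set.seed(2)
  a <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  expect_identical(smooth_gaussian(a, 0, c(1, 1, 1)), a)
  s <- smooth_gaussian(a, 1e4, c(1, 1, 1))
  expect_lt(max(abs(s - mean(a))), 1e-6)
})

test_that("rigid transforms compose rotation about a centre correctly", {
  tr <- rigid_from_params(angles_deg = c(0, 0, 90),
                          translation_mm = c(1, 0, 0),
                          center = c(10, 10, 0))
  # the centre itself only translates
  expect_equal(drop(apply_rigid(tr, c(10, 10, 0))), c(11, 10, 0),
               tolerance = 1e-12)
  # a point 5 mm along +x from the centre maps to +y
  expect_equal(drop(apply_rigid(tr, c(15, 10, 0))), c(11, 15, 0),
               tolerance = 1e-12)
})
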