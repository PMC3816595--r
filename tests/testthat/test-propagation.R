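test_that("mask propagation: identity, shift, and per-voxel oracle", {
  g <- image_grid(c(16, 16, 8), c(2, 2, 3))
  m <- random_blob_mask(g, seed = 5)
  expect_identical(propagate_mask(m, zero_field(g))$labels, m$labels)
  # constant one-voxel translation
  v <- array(0, c(g$dims, 3)); v[, , , 1] <- g$spacing[1]
  shifted <- propagate_mask(m, displacement_field(v, g))
  expect_identical(shifted$labels[1:15, , ], m$labels[2:16, , ])
  # random smooth field vs nested-loop oracle
  p <- grid_points(g)
  u <- cbind(1.2 * sin(p[, 2] / 10), 0.8 * cos(p[, 1] / 12),
             0.9 * sin(p[, 3] / 8))
  dvf <- displacement_field(array(u, c(g$dims, 3)), g)
  got <- propagate_mask(m, dvf)
  m_img <- scalar_image(m$labels + 0, g)
  want <- array(0L, g$dims)
  for (i in seq_len(nrow(p))) {
    s <- oracle_trilinear(m_img, p[i, ] + u[i, ], fill = 0)
    want[i] <- as.integer(s >= 0.5)
  }
  expect_identical(got$labels, want)
})

test_that("mask <-> mesh: cuboid volume, sphere round trip, error cases", {
  g <- image_grid(c(20, 20, 12), c(2, 2, 3))
  lab <- array(0L, g$dims); lab[5:12, 6:14, 4:9] <- 1L
  cuboid <- roi_mask(lab, g, "cuboid")
  msh <- mask_to_mesh(cuboid)
  expect_true(mesh_is_closed(msh))
  vox_vol <- sum(lab) * prod(g$spacing)
  expect_lt(abs(mesh_volume_mm3(msh) - vox_vol) / vox_vol, 0.05)
  # 10-voxel-radius sphere round trip
  gs <- image_grid(c(26, 26, 26), c(2, 2, 2))
  ps <- grid_points(gs)
  sph <- roi_mask(array(as.integer(rowSums(sweep(ps, 2, c(25, 25, 25))^2)
                                   <= 20^2), gs$dims), gs, "sphere")
  back <- mesh_to_mask(mask_to_mesh(sph), gs)
  expect_gte(dice(sph, back), 0.98)
  # errors
  expect_error(mask_to_mesh(roi_mask(array(0L, g$dims), g)), "empty")
  open_mesh <- contour_mesh(matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0), 3, 3,
                                   byrow = TRUE),
                            matrix(c(1, 2, 3), 1))
  expect_error(mesh_to_mask(open_mesh, g), "open mesh")
})

test_that("mesh propagation: identity, pure translation, direction flags", {
  g <- image_grid(c(16, 16, 12), c(2, 2, 3))
  m <- random_blob_mask(g, seed = 9)
  msh <- mask_to_mesh(m)
  set.seed(3)
  lm <- matrix(runif(30, 0, 30), 10, 3)
  # identity TPS
  tp_id <- fit_tps(lm, lm, 0, direction = "moving_to_fixed")
  out <- propagate_mesh(msh, tp_id)
  expect_equal(out$vertices, msh$vertices, tolerance = 1e-8)
  expect_identical(out$faces, msh$faces)
  expect_identical(out$frame, "fixed")
  # pure translation TPS moves every vertex exactly
  sh <- c(3, -2, 5)
  tp_t <- fit_tps(lm, sweep(lm, 2, sh, "+"), 0,
                  direction = "moving_to_fixed")
  out_t <- propagate_mesh(msh, tp_t)
  expect_equal(out_t$vertices, sweep(msh$vertices, 2, sh, "+"),
               tolerance = 1e-8)
  # direction flag mismatches are refused
  tp_wrong <- fit_tps(lm, lm, 0, direction = "fixed_to_moving")
  expect_error(propagate_mesh(msh, tp_wrong), "direction")
  fixed_mesh <- contour_mesh(msh$vertices, msh$faces, frame = "fixed")
  expect_error(propagate_mesh(fixed_mesh, tp_id), "direction")
})

test_that("mesh and mask routes agree under the same deformation", {
  # CT-resolution grid (the agreement bound holds where the voxel shell is
  # thin relative to the ROI; masks only, no image rasterisation needed)
  g <- image_grid(c(128, 128, 48), c(2, 2, 3))
  def <- small_bump()
  pts <- grid_points(g)
  gtv_ctr <- c(172, 115, 72)
  roi <- roi_mask(array(as.integer(
    rowSums(sweep(pts, 2, gtv_ctr)^2) <= 15^2), g$dims), g, "GTV")
  true_field <- sample_deformation(def, g)
  via_mask <- propagate_mask(roi, true_field)
  # mesh route: TPS fitted on moving -> fixed samples of the same map
  # (1000 landmarks keep the TPS interpolation error well under the voxel
  # size, so the two routes see the same deformation)
  set.seed(21)
  ext <- (g$dims - 1) * g$spacing
  fixed_pts <- sweep(matrix(runif(3000), 1000, 3), 2, ext, "*")
  moving_pts <- fixed_pts + def$u(fixed_pts)
  tp <- fit_tps(moving_pts, fixed_pts, lambda = 0,
                direction = "moving_to_fixed")
  via_mesh <- mesh_to_mask(propagate_mesh(mask_to_mesh(roi), tp), g)
  expect_gte(dice(via_mask, via_mesh), 0.95)
})
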