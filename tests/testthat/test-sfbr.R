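test_that("LoG blob detection finds a single Gaussian blob at the right scale", {
  g <- image_grid(c(48, 48, 32), c(2, 2, 2))
  p <- grid_points(g)
  sb <- 8
  ctr <- c(47, 47, 31)
  r2 <- (p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2 + (p[, 3] - ctr[3])^2
  img <- scalar_image(array(500 * exp(-r2 / (2 * sb^2)), g$dims), g)
  f <- detect_salient_features(img, sfbr_config(sigma_min_mm = 3,
                                                n_scales = 8))
  expect_equal(nrow(f), 1L)
  expect_lt(max(abs(c(f$x, f$y, f$z) - ctr)), max(g$spacing) + 1e-9)
  # scale ~ blob sigma * sqrt(3), within the half-octave ladder quantisation
  expect_gt(f$scale, sb * sqrt(3) / 2^0.25)
  expect_lt(f$scale, sb * sqrt(3) * 2^0.25)
  # flat image: no features
  flat <- scalar_image(array(5, g$dims), g)
  expect_equal(nrow(detect_salient_features(flat)), 0L)
})

test_that("feature matching: identity, translation recovery, degenerate gate", {
  # CT-like resolution so feature localisation is finer than the 2-mm
  # acceptance radius of the translation check
  spec <- phantom_spec(grid = image_grid(c(96, 96, 32), c(2.5, 2.5, 3)),
                       noise_sigma_hu = 5)
  img <- make_phantom(spec)$image
  cfg <- sfbr_config()
  f1 <- detect_salient_features(img, cfg)
  expect_gt(nrow(f1), 10)
  # identical feature lists match one-to-one onto themselves
  m_id <- match_features(f1, f1, cfg)
  expect_equal(nrow(m_id), nrow(f1))
  expect_equal(m_id$fx, m_id$mx)
  expect_equal(m_id$fz, m_id$mz)
  # known 5-mm translation: most matches within 2 mm of the truth
  shift <- c(5, 0, 0)
  pts <- grid_points(spec$grid)
  mt <- dirprop:::phantom_at(spec, sweep(pts, 2, shift, "+"), seed = 42L)$image
  f2 <- detect_salient_features(mt, cfg)
  m <- match_features(f1, f2, cfg)
  # feature at x in fixed appears at x - shift in the translated image
  disp <- cbind(m$mx - m$fx, m$my - m$fy, m$mz - m$fz)
  err <- sqrt(rowSums(sweep(disp, 2, -shift)^2))
  expect_gt(mean(err <= 2), 0.8)
  # ratio test 0 retains nothing
  expect_error(match_features(f1, f2, sfbr_config(match_ratio = 0)),
               "no correspondences")
  expect_error(match_features(f1[0, ], f2, cfg), "non-empty")
})

test_that("TPS: exact interpolation, affine reproduction, oracle agreement", {
  set.seed(7)
  src <- matrix(runif(60, 0, 100), 20, 3)
  tgt <- src + matrix(rnorm(60, 0, 3), 20, 3)
  tp <- fit_tps(src, tgt, lambda = 0)
  expect_lt(max(abs(evaluate_tps(tp, src) - tgt)), 1e-6)
  # side conditions: weights sum to zero and are moment-free
  P <- cbind(1, src)
  expect_lt(max(abs(t(P) %*% tp$weights)), 1e-8)
  # affine landmark set: zero kernel weights, affine part recovers the map
  A <- matrix(c(1.1, 0.1, 0, 0.05, 0.9, 0, 0, 0.02, 1.2), 3, 3)
  b <- c(5, -3, 2)
  tgt_a <- src %*% t(A) + matrix(b, 20, 3, byrow = TRUE)
  tp_a <- fit_tps(src, tgt_a, 0)
  expect_lt(max(abs(tp_a$weights)), 1e-6)
  expect_equal(unname(tp_a$affine[, 2:4]), A, tolerance = 1e-6)
  expect_equal(unname(tp_a$affine[, 1]), b, tolerance = 1e-6)
  # independent direct-summation oracle
  pts <- matrix(runif(30, 0, 100), 10, 3)
  got <- evaluate_tps(tp, pts)
  want <- t(vapply(seq_len(10), function(i) {
    r <- sqrt(colSums((t(src) - pts[i, ])^2))
    as.numeric(tp$affine[, 1] + tp$affine[, 2:4] %*% pts[i, ] +
               t(tp$weights) %*% r)
  }, numeric(3)))
  expect_lt(max(abs(got - want)), 1e-9)
  # batch evaluation equals per-point evaluation
  expect_equal(evaluate_tps(tp, pts[3, ]), got[3, , drop = FALSE])
  # degenerate inputs
  expect_error(fit_tps(src[1:4, ], tgt[1:4, ]), ">= 5")
  flat <- cbind(src[, 1:2], 0)
  expect_error(fit_tps(flat, tgt, 0), "coplanar|degenerate")
})

test_that("TPS bending energy: non-negative, zero iff affine, monotone in lambda", {
  set.seed(12)
  src <- matrix(runif(45, 0, 80), 15, 3)
  tgt <- src + matrix(rnorm(45, 0, 4), 15, 3)
  e0 <- tps_bending_energy(fit_tps(src, tgt, 0))
  expect_gt(e0, 0)
  lam <- c(0, 0.1, 1, 10, 100)
  energies <- vapply(lam, function(l)
    tps_bending_energy(fit_tps(src, tgt, l)), numeric(1))
  expect_true(all(diff(energies) <= 1e-9))
  # identity landmark set -> identity map
  tp_id <- fit_tps(src, src, 0)
  q <- matrix(runif(15, 0, 80), 5, 3)
  expect_equal(evaluate_tps(tp_id, q), q, tolerance = 1e-8)
  expect_lt(tps_bending_energy(tp_id), 1e-12)
})

test_that("feature detection is deterministic and capped", {
  spec <- small_phantom_spec(noise = 5)
  img <- make_phantom(spec)$image
  cfg <- sfbr_config(max_features = 25L)
  f1 <- detect_salient_features(img, cfg)
  f2 <- detect_salient_features(img, cfg)
  expect_identical(f1, f2)
  expect_lte(nrow(f1), 25L)
  # default cap sits inside the typical 1000-2000 operating range
  expect_gte(sfbr_config()$max_features, 1000L)
  expect_lte(sfbr_config()$max_features, 2000L)
})
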