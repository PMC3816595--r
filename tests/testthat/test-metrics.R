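grid8 <- image_grid(c(8, 8, 4), c(1, 1, 1))

cube_mask <- function(ix, iy, iz, grid = grid8, name = "cube") {
  lab <- array(0L, grid$dims)
  lab[ix, iy, iz] <- 1L
  roi_mask(lab, grid, name)
}

test_that("dice: identical, disjoint, hand-counted overlap", {
  a <- cube_mask(1:2, 1:2, 1:2)           # 8-voxel cube
  expect_equal(dice(a, a), 1)
  b <- cube_mask(5:6, 5:6, 3:4)
  expect_equal(dice(a, b), 0)
  # same cube shifted so the overlap is 4 voxels: 2*4/(8+8) = 0.5
  c_ <- cube_mask(1:2, 1:2, 2:3)
  expect_equal(dice(a, c_), 0.5)
  expect_error(dice(a, cube_mask(1:2, 1:2, 1:2, image_grid(c(8, 8, 5),
                                                           c(1, 1, 1)))),
               "grid")
  expect_warning(
    expect_equal(dice(roi_mask(array(0L, grid8$dims), grid8),
                      roi_mask(array(0L, grid8$dims), grid8)), 1), "empty")
})

test_that("mshd: trivial cases and slice handling", {
  a <- cube_mask(1:2, 1:2, 1:2)
  expect_equal(as.numeric(mshd(a, a)), 0)
  # two single-voxel contours 5 mm apart in plane on one slice
  g <- image_grid(c(10, 10, 1), c(1, 1, 1))
  p1 <- cube_mask(2, 2, 1, g); p2 <- cube_mask(7, 2, 1, g)
  expect_equal(as.numeric(mshd(p1, p2)), 5)
  # one-sided slices: excluded by default (count reported) or penalised
  a2 <- cube_mask(1:2, 1:2, 1:3)
  b2 <- cube_mask(1:2, 1:2, 1:2)
  m <- mshd(a2, b2)
  expect_equal(attr(m, "one_sided_slices"), 1L)
  expect_equal(as.numeric(m), 0)
  mp <- mshd(a2, b2, one_sided = "penalty", penalty_mm = 12)
  expect_equal(as.numeric(mp), (0 + 0 + 12) / 3)
  # no comparable slice -> error
  expect_error(mshd(cube_mask(1:2, 1:2, 1), cube_mask(1:2, 1:2, 2)),
               "comparable")
})

test_that("mshd equals the exhaustive all-pairs oracle and is symmetric", {
  g <- image_grid(c(32, 32, 4), c(0.98, 0.98, 3))
  for (s in 1:4) {
    a <- random_blob_mask(g, seed = 100 + s)
    b <- random_blob_mask(g, seed = 200 + s)
    both <- vapply(seq_len(4), function(k)
      any(a$labels[, , k] == 1L) && any(b$labels[, , k] == 1L), logical(1))
    if (!any(both)) next
    m_ab <- as.numeric(mshd(a, b))
    expect_equal(m_ab, oracle_mshd(a, b), tolerance = 1e-9)
    expect_equal(m_ab, as.numeric(mshd(b, a)), tolerance = 1e-12)
  }
})

test_that("com_distance reports centimetres between centroids", {
  a <- cube_mask(1:2, 1:2, 1:2)
  expect_equal(com_distance(a, a), 0)
  g <- image_grid(c(20, 4, 4), c(1, 1, 1))
  p1 <- cube_mask(2, 2, 2, g); p2 <- cube_mask(15, 2, 2, g)  # 13 mm apart
  expect_equal(com_distance(p1, p2), 1.3)
  # explicit centroid arithmetic on an asymmetric blob
  b <- cube_mask(1:3, 2, 2, g)
  c2 <- cube_mask(5, 3, 3, g)
  want <- sqrt(sum((c(2 - 5, 2 - 3, 2 - 3) * 1)^2)) / 10
  expect_equal(com_distance(b, c2), want, tolerance = 1e-12)
  expect_error(com_distance(a, roi_mask(array(0L, grid8$dims), grid8)),
               "empty")
})

test_that("volume_change_table reproduces the published per-patient rows", {
  v <- nsclc_gtv_volumes()
  res <- volume_change_table(v$pre_cm3, v$mid_cm3)
  expect_equal(res$table$percent_diff[1], 8.2)    # 15.8 -> 14.5
  expect_equal(res$table$percent_diff[3], -15.3)  # 96.6 -> 111.4
  expect_equal(res$table$percent_diff[8], -10.2)  # 59.6 -> 65.7
  expect_equal(volume_change_table(c(10, 20), c(10, 20))$table$percent_diff,
               c(0, 0))
  expect_error(volume_change_table(c(0, 1), c(1, 1)), "zero")
  expect_error(volume_change_table(1:3, 1:2), "length")
})

test_that("one-way ANOVA matches hand and lm() computations", {
  expect_error(one_way_anova(list(1:3)), "groups")
  expect_error(one_way_anova(list(1:3, 5)), "n >= 2")
  expect_error(one_way_anova(list(c(1, 1), c(2, 2))), "variance")
  # identical groups -> F = 0, p = 1
  r0 <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r0$F, 0)
  expect_equal(r0$p_value, 1)
  # hand calculation: {1,2,3} vs {4,5,6}: SSB 13.5, MSW 1 -> F 13.5
  r1 <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r1$F, 13.5)
  expect_true(r1$significant)
  # oracle: anova(lm(...)) on random unbalanced groups
  set.seed(4)
  gr <- list(rnorm(7), rnorm(5, 1), rnorm(9, 0.3))
  r2 <- one_way_anova(gr)
  d <- data.frame(y = unlist(gr),
                  g = factor(rep(seq_along(gr), lengths(gr))))
  ref <- anova(lm(y ~ g, d))
  expect_equal(r2$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(r2$p_value, ref$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("point-biserial equals the Pearson identity", {
  expect_error(point_biserial(c(1, 1, 1), 1:3), "classes")
  expect_equal(point_biserial(c(0, 0, 1, 1), c(5, 5, 5, 5))$r, 0)
  r1 <- point_biserial(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(abs(r1$r), 1)
  set.seed(8)
  g <- rbinom(40, 1, 0.4); g[1] <- 0; g[2] <- 1
  y <- rnorm(40) + 0.8 * g
  r2 <- point_biserial(g, y)
  ct <- cor.test(g, y)
  expect_equal(r2$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r2$p_value, ct$p.value, tolerance = 1e-9)
})

test_that("physician scores map to the 1 vs {2,3} grouping", {
  expect_equal(score_to_class(c(1, 2, 3, 1)), c(0L, 1L, 1L, 0L))
  expect_error(score_to_class(c(0, 1)), "scores")
})
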