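# Contour-agreement metrics (Dice, mean slicewise Hausdorff distance,
# centre-of-mass shift) and the cross-algorithm statistics used to compare
# propagated against physician-drawn ROIs.

#' Dice overlap score
#'
#' 2|A n B| / (|A| + |B|) on voxel counts.  Two empty masks are defined as
#' perfectly agreeing (Dice 1) with a warning.
#'
#' @param a,b `roi_mask`s on the same grid.
#' @return unitless value in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!grids_equal(a$grid, b$grid)) stop("masks must share a grid")
  na <- sum(a$labels); nb <- sum(b$labels)
  if (na + nb == 0L) {
    warning("both masks empty: Dice defined as 1")
    return(1)
  }
  2 * sum(a$labels & b$labels) / (na + nb)
}

# in-plane (2-D, 4-connectivity) boundary voxel centres of slice k, world mm
slice_boundary_points <- function(mask, k) {
  s <- mask$labels[, , k]
  if (!any(s == 1L)) return(NULL)
  d <- dim(s)
  pad <- matrix(0L, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- s
  inner <- pad[2:(d[1] + 1L), 2:(d[2] + 1L)] == 1L &
    pad[1:d[1], 2:(d[2] + 1L)] == 1L & pad[3:(d[1] + 2L), 2:(d[2] + 1L)] == 1L &
    pad[2:(d[1] + 1L), 1:d[2]] == 1L & pad[2:(d[1] + 1L), 3:(d[2] + 2L)] == 1L
  idx <- which(s == 1L & !inner, arr.ind = TRUE)
  cbind(mask$grid$origin[1] + (idx[, 1] - 1L) * mask$grid$spacing[1],
        mask$grid$origin[2] + (idx[, 2] - 1L) * mask$grid$spacing[2])
}

# symmetric 2-D Hausdorff distance between two point sets (rows = points)
hausdorff_2d <- function(pa, pb) {
  dx <- outer(pa[, 1], pb[, 1], "-")
  dy <- outer(pa[, 2], pb[, 2], "-")
  d2 <- dx * dx + dy * dy
  sqrt(max(apply(d2, 1, min), apply(d2, 2, min)))
}

#' Mean slicewise Hausdorff distance (MSHD)
#'
#' Per axial slice on which BOTH masks are non-empty, the symmetric
#' Hausdorff distance between the two in-plane boundary point sets
#' (boundary voxel centres, world mm); the MSHD is the mean over those
#' slices.  Slices where exactly one mask is present are excluded from the
#' mean by default (their count is reported in the "one_sided_slices"
#' attribute); alternatively a fixed penalty distance can be charged.
#'
#' @param a,b `roi_mask`s on the same grid.
#' @param one_sided "exclude" (default) or "penalty".
#' @param penalty_mm distance charged per one-sided slice when
#'   `one_sided = "penalty"`.
#' @return MSHD in mm with attributes "n_slices" and "one_sided_slices".
#' @export
mshd <- function(a, b, one_sided = c("exclude", "penalty"), penalty_mm = 10) {
  one_sided <- match.arg(one_sided)
  if (!grids_equal(a$grid, b$grid)) stop("masks must share a grid")
  nz <- a$grid$dims[3]
  hd <- numeric(0); n_one <- 0L
  for (k in seq_len(nz)) {
    pa <- slice_boundary_points(a, k)
    pb <- slice_boundary_points(b, k)
    if (is.null(pa) && is.null(pb)) next
    if (is.null(pa) || is.null(pb)) { n_one <- n_one + 1L; next }
    hd <- c(hd, hausdorff_2d(pa, pb))
  }
  if (one_sided == "penalty") hd <- c(hd, rep(penalty_mm, n_one))
  if (length(hd) == 0L) stop("no comparable slices")
  structure(mean(hd), n_slices = length(hd), one_sided_slices = n_one)
}

#' Centre-of-mass distance between two masks (cm)
#'
#' Euclidean distance between the unweighted voxel-centroid positions,
#' reported in cm (the unit used for isocentre-shift assessment).
#' @param a,b non-empty `roi_mask`s.
#' @export
com_distance <- function(a, b) {
  if (sum(a$labels) == 0L || sum(b$labels) == 0L) stop("empty mask")
  com <- function(m) {
    idx <- which(m$labels == 1L, arr.ind = TRUE)
    m$grid$origin + (colMeans(idx) - 1) * m$grid$spacing
  }
  sqrt(sum((com(a) - com(b))^2)) / 10
}

#' GTV volumes of a published 17-patient NSCLC adaptive-radiotherapy cohort
#'
#' Pre- and mid-treatment gross tumour volumes (cm^3) reported for 17
#' non-small-cell lung cancer patients rescanned during the second week of
#' radiotherapy.  Used as the reference input for the volume-change
#' statistics and as the target volume-change distribution emulated by the
#' phantom cohort generator.
#'
#' @return data.frame with columns patient, pre_cm3, mid_cm3 and the
#'   percent difference as published (positive = shrinkage).
#' @export
nsclc_gtv_volumes <- function() {
  data.frame(
    patient = 1:17,
    pre_cm3 = c(15.8, 150.5, 96.6, 39.4, 32.9, 7.9, 55.8, 59.6, 158.6,
                18.7, 115.7, 17.9, 3.1, 182.1, 46.3, 10.9, 66.6),
    mid_cm3 = c(14.5, 106.2, 111.4, 39, 26.4, 7.8, 47, 65.7, 120.9,
                17.2, 104.3, 17.3, 2.9, 148.8, 56.9, 10.3, 65.5),
    percent_diff_published = c(8.2, 29.4, -15.3, 1.0, 19.8, 1.3, 15.8,
                               -10.2, 23.8, 8.0, 9.9, 3.4, 6.5, 18.3,
                               -22.9, 5.5, 1.7))
}

#' Volume-change table and summary statistics
#'
#' Per-patient percent difference 100 (pre - mid) / pre (positive =
#' shrinkage), rounded to one decimal, plus the column means and the counts
#' of volume decreases, increases, and increases larger than 10%.
#'
#' @param pre_volumes,mid_volumes equal-length vectors of volumes (cm^3).
#' @return list with `table` (data.frame patient/pre/mid/percent_diff) and
#'   `summary` (mean_pre, mean_mid, mean_percent_diff, n_decrease,
#'   n_increase, n_increase_gt10).
#' @export
volume_change_table <- function(pre_volumes, mid_volumes) {
  pre <- as.numeric(pre_volumes); mid <- as.numeric(mid_volumes)
  if (length(pre) != length(mid)) stop("volume lists must have equal length")
  if (any(pre == 0)) stop("zero pre-treatment volume")
  pct <- round(100 * (pre - mid) / pre, 1)
  tab <- data.frame(patient = seq_along(pre), pre_cm3 = pre, mid_cm3 = mid,
                    percent_diff = pct)
  list(table = tab,
       summary = list(mean_pre = round(mean(pre), 2),
                      mean_mid = round(mean(mid), 2),
                      mean_percent_diff = round(mean(pct), 1),
                      n_decrease = sum(mid < pre),
                      n_increase = sum(mid > pre),
                      n_increase_gt10 = sum(mid > pre & pct < -10)))
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F statistic with the F-distribution
#' p-value; significance is flagged at p = 0.05.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @param alpha significance threshold (default 0.05).
#' @return list(F, p_value, df, significant).
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  n_i <- lengths(groups)
  if (any(n_i < 2L)) stop("each group needs n >= 2")
  k <- length(groups); N <- sum(n_i)
  m_i <- vapply(groups, mean, numeric(1))
  grand <- sum(n_i * m_i) / N
  ssb <- sum(n_i * (m_i - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0) stop("zero within-group variance everywhere")
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  f <- msb / msw
  p <- stats::pf(f, k - 1, N - k, lower.tail = FALSE)
  list(F = f, p_value = p, df = c(k - 1, N - k), significant = p < alpha)
}

#' Map physician utility scores to point-biserial classes
#'
#' Score 1 ("clinically acceptable without modification") maps to class 0;
#' scores 2 and 3 (minor / major edits required) map to class 1.
#' @param scores integer vector with values in \{1, 2, 3\}.
#' @export
score_to_class <- function(scores) {
  if (!all(scores %in% 1:3)) stop("scores must be 1, 2 or 3")
  as.integer(scores >= 2L)
}

#' Point-biserial correlation
#'
#' r_pb = (M1 - M0)/s * sqrt(n1 n0 / n^2) with s the full-sample
#' (population, denominator n) standard deviation; algebraically identical
#' to the Pearson correlation of the values with the binary indicator.
#' The p-value comes from the equivalent two-sample t test with n - 2 df.
#'
#' @param binary_group vector of 0/1 class labels.
#' @param values numeric vector of metric values.
#' @return list(r, p_value).
#' @export
point_biserial <- function(binary_group, values) {
  g <- as.integer(binary_group)
  if (!all(g %in% c(0L, 1L))) stop("binary_group must be 0/1")
  if (length(g) != length(values)) stop("length mismatch")
  n1 <- sum(g == 1L); n0 <- sum(g == 0L); n <- n1 + n0
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  s <- sqrt(mean((values - mean(values))^2))
  if (s == 0) return(list(r = 0, p_value = 1))
  r <- (mean(values[g == 1L]) - mean(values[g == 0L])) / s *
    sqrt(n1 * n0 / n^2)
  tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
  p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  list(r = r, p_value = p)
}
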