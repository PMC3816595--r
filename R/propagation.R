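# ROI propagation from the pre-treatment (moving) frame to the
# mid-treatment (fixed) frame: binary masks are pulled back through a
# displacement field; meshes are carried forward vertex-wise through a
# moving -> fixed TPS.  No smoothing is applied to propagated ROIs.

#' Propagate a binary mask through a displacement field
#'
#' For every fixed-grid voxel centre x the pre-treatment mask is sampled
#' trilinearly at x + u(x); the voxel is labelled 1 iff the sampled value
#' is >= 0.5 (the unbiased iso-level for binary data).  If a rigid
#' pre-alignment was used during registration, pass it so the total map
#' x -> R(x + u(x)) + t reaches the original pre-treatment frame.
#'
#' @param mask_pre `roi_mask` on the pre-treatment grid.
#' @param dvf `displacement_field` on the fixed grid.
#' @param rigid optional `rigid_transform` (fixed -> moving) composed after
#'   the field.
#' @return `roi_mask` on the fixed grid.
#' @export
propagate_mask <- function(mask_pre, dvf, rigid = NULL) {
  pts <- grid_points(dvf$grid) + field_matrix(dvf)
  if (!is.null(rigid)) pts <- apply_rigid(rigid, pts)
  m_img <- scalar_image(mask_pre$labels + 0, mask_pre$grid)
  vals <- trilinear_sample(m_img, pts, fill = 0)
  roi_mask(array(as.integer(vals >= 0.5), dvf$grid$dims), dvf$grid,
           mask_pre$name)
}

#' Extract the closed surface mesh of a binary mask
#'
#' Marching-tetrahedra isosurface at level 0.5: every 2x2x2 cell of voxel
#' centres is split into six tetrahedra (sharing the main diagonal, so
#' neighbouring cells triangulate their common face identically and the
#' mesh is watertight), and each mixed tetrahedron contributes triangles
#' whose vertices are the 0.5 crossings - edge midpoints for binary data -
#' approximating the trilinear 0.5 level set that mask pull-back
#' thresholds.  The volume is zero-padded first so the surface closes at
#' the grid boundary.
#'
#' @param mask non-empty `roi_mask`.
#' @param frame frame tag for the resulting mesh (default "moving").
#' @return `contour_mesh` with outward-oriented faces.
#' @export
mask_to_mesh <- function(mask, frame = "moving") {
  if (sum(mask$labels) == 0L) stop("empty mask")
  g <- mask$grid
  d <- g$dims
  pd <- d + 2L
  lab <- array(0L, pd)
  lab[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask$labels
  # world coordinates of padded voxel centres, component by component
  cx <- g$origin[1] + (seq_len(pd[1]) - 2L) * g$spacing[1]
  cy <- g$origin[2] + (seq_len(pd[2]) - 2L) * g$spacing[2]
  cz <- g$origin[3] + (seq_len(pd[3]) - 2L) * g$spacing[3]
  # mixed cells: 2x2x2 neighbourhoods containing both labels
  sub <- function(a, i, j, k) a[i, j, k]
  i0 <- seq_len(pd[1] - 1L); j0 <- seq_len(pd[2] - 1L); k0 <- seq_len(pd[3] - 1L)
  s_ <- function(di, dj, dk) sub(lab, i0 + di, j0 + dj, k0 + dk)
  tot <- s_(0,0,0) + s_(1,0,0) + s_(0,1,0) + s_(1,1,0) +
         s_(0,0,1) + s_(1,0,1) + s_(0,1,1) + s_(1,1,1)
  mixed <- which(tot > 0L & tot < 8L, arr.ind = TRUE)
  if (nrow(mixed) == 0L) stop("empty mask")
  lin <- function(i, j, k)
    as.integer(i + pd[1] * (j - 1L) + pd[1] * pd[2] * (k - 1L))
  # cube corner offsets (standard order) and 6-tet decomposition along 0-6
  corner_off <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
                      c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  tets <- rbind(c(1,2,3,7), c(1,3,4,7), c(1,4,8,7),
                c(1,8,5,7), c(1,5,6,7), c(1,6,2,7))
  corn <- vapply(seq_len(8), function(c_)
    lin(mixed[, 1] + corner_off[c_, 1], mixed[, 2] + corner_off[c_, 2],
        mixed[, 3] + corner_off[c_, 3]), integer(nrow(mixed)))
  if (is.null(dim(corn))) corn <- matrix(corn, nrow = 1L)
  # all tets of mixed cells: n_cell*6 rows of padded linear corner indices
  Tm <- do.call(rbind, lapply(seq_len(6), function(t_)
    corn[, tets[t_, ], drop = FALSE]))
  V <- matrix(lab[Tm], ncol = 4L)
  code <- V %*% c(1L, 2L, 4L, 8L)
  # per-code triangle recipes: triangles as triples of edges (corner-slot
  # pairs); orientation fixed afterwards from the inside->outside direction
  tri_edges <- function(a, b, c_, d_)  # a inside, rest outside (or inverse)
    list(rbind(c(a, b), c(a, c_), c(a, d_)))
  quad_edges <- function(a, b, c_, d_)  # a,b inside; c_,d_ outside
    list(rbind(c(a, c_), c(a, d_), c(b, d_)),
         rbind(c(a, c_), c(b, d_), c(b, c_)))
  recipes <- list(
    `1` = tri_edges(1, 2, 3, 4), `2` = tri_edges(2, 1, 3, 4),
    `4` = tri_edges(3, 1, 2, 4), `8` = tri_edges(4, 1, 2, 3),
    `14` = tri_edges(1, 2, 3, 4), `13` = tri_edges(2, 1, 3, 4),
    `11` = tri_edges(3, 1, 2, 4), `7` = tri_edges(4, 1, 2, 3),
    `3` = quad_edges(1, 2, 3, 4), `12` = quad_edges(3, 4, 1, 2),
    `5` = quad_edges(1, 3, 2, 4), `10` = quad_edges(2, 4, 1, 3),
    `9` = quad_edges(1, 4, 2, 3), `6` = quad_edges(2, 3, 1, 4))
  pos_of <- function(idx) {
    i <- (idx - 1L) %% pd[1] + 1L
    j <- ((idx - 1L) %/% pd[1]) %% pd[2] + 1L
    k <- (idx - 1L) %/% (pd[1] * pd[2]) + 1L
    cbind(cx[i], cy[j], cz[k])
  }
  e1k <- integer(0); e2k <- integer(0); e3k <- integer(0)  # edge keys/tri
  for (cd in names(recipes)) {
    rows <- which(code == as.integer(cd))
    if (!length(rows)) next
    Tc <- Tm[rows, , drop = FALSE]
    Vc <- V[rows, , drop = FALSE]
    for (tri in recipes[[cd]]) {
      # edge endpoints as padded linear indices
      eA <- cbind(Tc[, tri[1, 1]], Tc[, tri[1, 2]])
      eB <- cbind(Tc[, tri[2, 1]], Tc[, tri[2, 2]])
      eC <- cbind(Tc[, tri[3, 1]], Tc[, tri[3, 2]])
      pA <- (pos_of(eA[, 1]) + pos_of(eA[, 2])) / 2
      pB <- (pos_of(eB[, 1]) + pos_of(eB[, 2])) / 2
      pC <- (pos_of(eC[, 1]) + pos_of(eC[, 2])) / 2
      # orient: normal must point from the inside corners to the outside
      n1 <- pB - pA; n2 <- pC - pA
      nrm <- cbind(n1[, 2] * n2[, 3] - n1[, 3] * n2[, 2],
                   n1[, 3] * n2[, 1] - n1[, 1] * n2[, 3],
                   n1[, 1] * n2[, 2] - n1[, 2] * n2[, 1])
      ctr_in <- ctr_out <- matrix(0, length(rows), 3)
      w_in <- rowSums(Vc); w_out <- 4 - w_in
      for (c_ in 1:4) {
        pc <- pos_of(Tc[, c_])
        ctr_in <- ctr_in + pc * Vc[, c_]
        ctr_out <- ctr_out + pc * (1 - Vc[, c_])
      }
      ref <- ctr_out / w_out - ctr_in / w_in
      flip <- rowSums(nrm * ref) < 0
      eB2 <- eB; eC2 <- eC
      eB[flip, ] <- eC2[flip, ]; eC[flip, ] <- eB2[flip, ]
      key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      e1k <- c(e1k, key(eA)); e2k <- c(e2k, key(eB)); e3k <- c(e3k, key(eC))
    }
  }
  all_keys <- c(e1k, e2k, e3k)
  ukeys <- unique(all_keys)
  fidx <- matrix(match(all_keys, ukeys), ncol = 3L)
  ends <- matrix(as.integer(unlist(strsplit(ukeys, " ", fixed = TRUE))),
                 ncol = 2L, byrow = TRUE)
  vtx <- (pos_of(ends[, 1]) + pos_of(ends[, 2])) / 2
  contour_mesh(vtx, fidx, frame = frame)
}

#' Voxelise a closed mesh onto a grid
#'
#' Labels the voxels whose centres lie inside the closed surface, decided
#' by the parity of ray-triangle crossings along +x (ray origins are
#' jittered by a sub-micron irrational offset to avoid edge-through-vertex
#' degeneracies).
#'
#' @param mesh closed `contour_mesh`.
#' @param grid target `image_grid`.
#' @param name ROI name for the result.
#' @return `roi_mask`.
#' @export
mesh_to_mask <- function(mesh, grid, name = "ROI") {
  if (!mesh_is_closed(mesh)) stop("open mesh passed to voxelization")
  d <- grid$dims
  eps_y <- 1.23456789e-4 * grid$spacing[2]
  eps_z <- 0.98765432e-4 * grid$spacing[3]
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2] + eps_y
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3] + eps_z
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  # per-(j,k) ray: collect x crossings
  crossings <- vector("list", d[2] * d[3])
  v <- mesh$vertices
  f <- mesh$faces
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  for (t_ in seq_len(nrow(f))) {
    a <- A[t_, ]; b <- B[t_, ]; c_ <- C[t_, ]
    e1 <- b - a; e2 <- c_ - a
    det <- e1[2] * e2[3] - e1[3] * e2[2]
    if (abs(det) < 1e-12) next  # projection degenerate along x
    jy <- which(ys >= min(a[2], b[2], c_[2]) & ys <= max(a[2], b[2], c_[2]))
    kz <- which(zs >= min(a[3], b[3], c_[3]) & zs <= max(a[3], b[3], c_[3]))
    if (!length(jy) || !length(kz)) next
    for (k in kz) {
      dz <- zs[k] - a[3]
      for (j in jy) {
        dy <- ys[j] - a[2]
        beta <- (dy * e2[3] - dz * e2[2]) / det
        if (beta < 0 || beta > 1) next
        gama <- (e1[2] * dz - e1[3] * dy) / det
        if (gama < 0 || beta + gama > 1) next
        xc <- a[1] + beta * e1[1] + gama * e2[1]
        ridx <- j + (k - 1L) * d[2]
        crossings[[ridx]] <- c(crossings[[ridx]], xc)
      }
    }
  }
  lab <- array(0L, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) {
    cr <- crossings[[j + (k - 1L) * d[2]]]
    if (is.null(cr)) next
    parity <- findInterval(xs, sort(cr)) %% 2L
    lab[, j, k] <- parity
  }
  roi_mask(lab, grid, name)
}

#' Propagate a mesh through a thin-plate-spline transform
#'
#' Applies the TPS vertex-wise; faces are unchanged and no smoothing is
#' performed.  The mesh lives in the pre-treatment (moving) frame, so the
#' transform must have been fitted in the propagation direction
#' (`moving_to_fixed`, i.e. on reversed correspondences); a mismatching
#' direction flag is an error.
#'
#' @param mesh_pre `contour_mesh` in the moving frame.
#' @param tps `tps_transform` with direction "moving_to_fixed".
#' @return `contour_mesh` in the fixed frame.
#' @export
propagate_mesh <- function(mesh_pre, tps) {
  if (!identical(mesh_pre$frame, "moving"))
    stop("direction flag mismatch: mesh must be in the moving frame")
  if (!identical(tps$direction, "moving_to_fixed"))
    stop("direction flag mismatch: TPS must map moving -> fixed")
  contour_mesh(evaluate_tps(tps, mesh_pre$vertices), mesh_pre$faces,
               frame = "fixed")
}
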