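# Grid-based active-site pocket volumetrics. The cofactor is removed in
# silico, space is discretized on a cubic grid, solvent accessibility is
# defined by a 1.4 A probe, pocket mouths are sealed by morphological
# closing with a larger closure probe, and the re-entrant pocket volume is
# reported in cubic Angstrom.

# ---- voxel-mask primitives ------------------------------------------------

# Precompute integer offsets (di, dj, dk) within a ball of radius r voxels.
.ball_offsets <- function(r_vox) {
  r <- ceiling(r_vox)
  g <- expand.grid(di = -r:r, dj = -r:r, dk = -r:r)
  keep <- g$di^2 + g$dj^2 + g$dk^2 <= r_vox^2
  as.matrix(g[keep, , drop = FALSE])
}

# Stamp balls of radius r_vox (voxels) around the given voxel linear
# indices. `dims` are the grid dims; indices falling outside are dropped.
.stamp_ball <- function(mask, centers_lin, r_vox, dims) {
  if (length(centers_lin) == 0L) return(mask)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  k0 <- (centers_lin - 1L) %/% (nx * ny)
  rem <- (centers_lin - 1L) %% (nx * ny)
  j0 <- rem %/% nx
  i0 <- rem %% nx
  off <- .ball_offsets(r_vox)
  for (o in seq_len(nrow(off))) {
    i <- i0 + off[o, 1]; j <- j0 + off[o, 2]; k <- k0 + off[o, 3]
    ok <- i >= 0L & i < nx & j >= 0L & j < ny & k >= 0L & k < nz
    if (!any(ok)) next
    mask[1L + i[ok] + nx * (j[ok] + ny * k[ok])] <- TRUE
  }
  mask
}

# 6-neighbor surface of a mask: mask voxels with at least one complement
# (or out-of-grid) 6-neighbor.
.mask_surface <- function(mask, dims) {
  a <- array(mask, dim = dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  surf <- array(FALSE, dim = dims)
  # a neighbor outside the grid counts as complement
  surf[1, , ] <- surf[1, , ] | a[1, , ]
  surf[nx, , ] <- surf[nx, , ] | a[nx, , ]
  surf[, 1, ] <- surf[, 1, ] | a[, 1, ]
  surf[, ny, ] <- surf[, ny, ] | a[, ny, ]
  surf[, , 1] <- surf[, , 1] | a[, , 1]
  surf[, , nz] <- surf[, , nz] | a[, , nz]
  surf[-nx, , ] <- surf[-nx, , ] | (a[-nx, , ] & !a[-1, , ])
  surf[-1, , ]  <- surf[-1, , ]  | (a[-1, , ]  & !a[-nx, , ])
  surf[, -ny, ] <- surf[, -ny, ] | (a[, -ny, ] & !a[, -1, ])
  surf[, -1, ]  <- surf[, -1, ]  | (a[, -1, ]  & !a[, -ny, ])
  surf[, , -nz] <- surf[, , -nz] | (a[, , -nz] & !a[, , -1])
  surf[, , -1]  <- surf[, , -1]  | (a[, , -1]  & !a[, , -nz])
  as.logical(surf)
}

# Morphological dilation by a ball: mask plus balls stamped on its surface.
.dilate_mask <- function(mask, r_vox, dims) {
  if (r_vox <= 0) return(mask)
  surf <- .mask_surface(mask, dims)
  .stamp_ball(mask, which(surf), r_vox, dims)
}

# Erosion via complement: voxels of the mask farther than r from the
# complement (out-of-grid counts as complement).
.erode_mask <- function(mask, r_vox, dims) {
  if (r_vox <= 0) return(mask)
  !.dilate_mask(!mask, r_vox, dims)
}

# 6-connected flood fill over `space` from the given seed linear indices.
.flood_fill <- function(space, seeds_lin, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  visited <- logical(length(space))
  seeds_lin <- seeds_lin[space[seeds_lin]]
  seeds_lin <- unique(seeds_lin)
  visited[seeds_lin] <- TRUE
  frontier <- seeds_lin
  nxny <- nx * ny
  while (length(frontier) > 0L) {
    k0 <- (frontier - 1L) %/% nxny
    rem <- (frontier - 1L) %% nxny
    j0 <- rem %/% nx
    i0 <- rem %% nx
    cand <- c(frontier[i0 > 0L] - 1L, frontier[i0 < nx - 1L] + 1L,
              frontier[j0 > 0L] - nx, frontier[j0 < ny - 1L] + nx,
              frontier[k0 > 0L] - nxny, frontier[k0 < nz - 1L] + nxny)
    cand <- cand[space[cand] & !visited[cand]]
    cand <- unique(cand)
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

# linear indices of all voxels on the grid boundary faces
.boundary_lin <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  idx <- array(seq_len(nx * ny * nz), dim = dims)
  unique(c(idx[1, , ], idx[nx, , ], idx[, 1, ], idx[, ny, ],
           idx[, , 1], idx[, , nz]))
}

# ---- grid construction ----------------------------------------------------

#' Build the occupancy grid of a structure
#'
#' Discretizes space on a cubic grid covering all retained heavy atoms plus
#' a margin. A voxel is `occupied` when its center lies within the van der
#' Waals radius of a retained atom, and `blocked` when within vdW + probe
#' (probe centers cannot enter blocked voxels). Hydrogens and atoms of the
#' `exclude` group are removed before gridding.
#'
#' @param structure a `metcof_structure`.
#' @param exclude optional `metcof_cofactor` whose atoms are removed (the
#'   in-silico cofactor extraction).
#' @param spacing voxel edge in Angstrom, in (0.1, 1].
#' @param probe solvent probe radius in Angstrom (default 1.4, water).
#' @param margin grid margin beyond the atom bounding box; default is large
#'   enough for the vdW + probe stamps and the default closure probe.
#' @return a `metcof_grid`: `origin` (center of voxel \[1,1,1\]), `spacing`,
#'   `dims`, `occupied`, `blocked` (logical vectors of length prod(dims)),
#'   `exclude_centroid`.
#' @export
build_occupancy <- function(structure, exclude = NULL, spacing = 0.5,
                            probe = 1.4, margin = NULL) {
  stopifnot(inherits(structure, "metcof_structure"),
            spacing > 0.1, spacing <= 1.0, probe >= 0)
  at <- structure$atoms
  at <- at[at$element != "H", , drop = FALSE]
  centroid <- NULL
  if (!is.null(exclude)) {
    centroid <- colMeans(exclude$atoms[, c("x", "y", "z")])
    at <- at[!(at$serial %in% exclude$atoms$serial), , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no atoms left to grid")
  maxv <- max(at$vdw)
  if (is.null(margin)) margin <- maxv + probe + 4.0 + 2 * spacing
  stopifnot(margin >= maxv + probe)
  lo <- c(min(at$x), min(at$y), min(at$z)) - margin
  hi <- c(max(at$x), max(at$y), max(at$z)) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  origin <- lo
  nvox <- prod(dims)
  occupied <- logical(nvox)
  blocked <- logical(nvox)
  ix <- as.integer(round((at$x - origin[1]) / spacing))
  iy <- as.integer(round((at$y - origin[2]) / spacing))
  iz <- as.integer(round((at$z - origin[3]) / spacing))
  lin <- 1L + ix + dims[1] * (iy + dims[2] * iz)
  # stamp per distinct radius so ball offsets are computed once each
  for (r in unique(at$vdw)) {
    sel <- at$vdw == r
    occupied <- .stamp_ball(occupied, lin[sel], r / spacing, dims)
    blocked <- .stamp_ball(blocked, lin[sel], (r + probe) / spacing, dims)
  }
  structure(
    list(origin = origin, spacing = spacing, dims = dims,
         occupied = occupied, blocked = blocked, probe = probe,
         exclude_centroid = centroid),
    class = "metcof_grid"
  )
}

# nearest voxel linear index to an Angstrom-space point
.point_to_lin <- function(grid, p) {
  idx <- pmin(pmax(as.integer(round((p - grid$origin) / grid$spacing)), 0L),
              grid$dims - 1L)
  1L + idx[1] + grid$dims[1] * (idx[2] + grid$dims[2] * idx[3])
}

#' Detect the pocket containing a seed point and measure its volume
#'
#' Probe-center accessible space is the complement of the blocked mask. The
#' exterior is found by flood filling accessible space from the grid
#' boundary after morphological closing with `closure_probe` (which seals
#' pocket mouths). The pocket is the accessible connected component holding
#' the seed, minus the exterior; the reported volume is that component
#' dilated by the probe and intersected with unoccupied voxels (re-entrant
#' volume).
#'
#' @param grid a `metcof_grid` from [build_occupancy()].
#' @param seed 3-vector (Angstrom) inside the pocket; defaults to the
#'   centroid of the excluded cofactor.
#' @param closure_probe mouth-sealing ball radius in Angstrom (default 4).
#' @return a `metcof_pocket`: `volume` (A^3), `voxel_count`, `spacing`,
#'   `probe`, `closure_probe`, `seed`, `open_to_solvent`, and `voxels`
#'   (linear indices of the counted volume voxels).
#' @export
detect_pocket <- function(grid, seed = NULL, closure_probe = 4.0) {
  stopifnot(inherits(grid, "metcof_grid"), closure_probe >= 0)
  if (is.null(seed)) seed <- grid$exclude_centroid
  if (is.null(seed)) stop("no seed point: supply one or build the grid with an exclude group")
  dims <- grid$dims
  sp <- grid$spacing
  accessible <- !grid$blocked
  seed_lin <- .point_to_lin(grid, seed)
  if (!accessible[seed_lin]) {
    # snap to the nearest accessible voxel within 3 A
    r <- ceiling(3 / sp)
    near <- logical(length(accessible))
    near <- .stamp_ball(near, seed_lin, 3 / sp, dims)
    cand <- which(near & accessible)
    if (length(cand) == 0L)
      stop("seed lies in blocked space and no accessible voxel within 3 A")
    k0 <- (cand - 1L) %/% (dims[1] * dims[2])
    rem <- (cand - 1L) %% (dims[1] * dims[2])
    cxyz <- cbind(rem %% dims[1], rem %/% dims[1], k0) * sp +
      matrix(grid$origin, length(cand), 3, byrow = TRUE)
    sd2 <- rowSums((cxyz - matrix(seed, length(cand), 3, byrow = TRUE))^2)
    seed_lin <- cand[which.min(sd2)]
  }
  comp_all <- .flood_fill(accessible, seed_lin, dims)
  blin <- .boundary_lin(dims)
  if (!any(comp_all[blin])) {
    # fully enclosed pocket: no mouth to seal, skip the (costly) closing
    exterior <- .flood_fill(accessible, blin, dims)
  } else {
    closed_blocked <- .erode_mask(
      .dilate_mask(grid$blocked, closure_probe / sp, dims),
      closure_probe / sp, dims)
    exterior <- .flood_fill(!closed_blocked, blin, dims)
  }
  open <- any(comp_all & exterior)
  core_space <- accessible & !exterior
  if (core_space[seed_lin]) {
    core <- .flood_fill(core_space, seed_lin, dims)
  } else {
    core <- logical(length(accessible))
  }
  # +0.5 voxel: midpoint compensation for the quantization of the region
  # boundary to surface-voxel centers (the continuous boundary lies up to
  # one voxel outside them)
  vol_mask <- .dilate_mask(core, grid$probe / sp + 0.5, dims) & !grid$occupied
  nv <- sum(vol_mask)
  structure(
    list(volume = nv * sp^3, voxel_count = nv, spacing = sp,
         probe = grid$probe, closure_probe = closure_probe,
         seed = seed, open_to_solvent = open, voxels = which(vol_mask),
         dims = dims, origin = grid$origin),
    class = "metcof_pocket"
  )
}

#' @export
print.metcof_pocket <- function(x, ...) {
  cat(sprintf("<metcof_pocket> volume %.1f A^3 (%d voxels at %.2f A, probe %.1f A)%s\n",
              x$volume, x$voxel_count, x$spacing, x$probe,
              if (x$open_to_solvent) " [open to solvent]" else ""))
  invisible(x)
}

#' Active-site pocket volume after cofactor removal
#'
#' Convenience composition of [build_occupancy()] and [detect_pocket()]:
#' removes the cofactor, grids the remaining structure and measures the
#' pocket seeded at the cofactor centroid.
#'
#' @inheritParams build_occupancy
#' @param cofactor the `metcof_cofactor` removed before gridding; its
#'   centroid seeds the pocket search.
#' @param closure_probe mouth-sealing ball radius in Angstrom (default 4).
#' @return a `metcof_pocket`.
#' @export
pocket_volume <- function(structure, cofactor, probe = 1.4, spacing = 0.5,
                          closure_probe = 4.0) {
  grid <- build_occupancy(structure, exclude = cofactor, spacing = spacing,
                          probe = probe)
  detect_pocket(grid, closure_probe = closure_probe)
}

#' Write pocket voxels as a pseudo-atom PDB for visualization
#'
#' @param pocket a `metcof_pocket`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_pocket_pdb <- function(pocket, path) {
  lin <- pocket$voxels - 1L
  nx <- pocket$dims[1]; ny <- pocket$dims[2]
  k <- lin %/% (nx * ny); rem <- lin %% (nx * ny)
  xyz <- cbind(rem %% nx, rem %/% nx, k) * pocket$spacing +
    matrix(pocket$origin, length(lin), 3, byrow = TRUE)
  n <- nrow(xyz)
  suppressWarnings(bio3d::write.pdb(
    file = path, xyz = as.numeric(t(xyz)),
    type = rep("HETATM", n), resno = rep(1L, n), resid = rep("PKT", n),
    eleno = seq_len(n), elety = rep("DUM", n), chain = rep("Z", n),
    o = rep(1, n), b = rep(0, n), elesy = rep("X", n)
  ))
  invisible(path)
}

#' Aggregate pocket volumes per class
#'
#' Mean and average deviation (mean absolute deviation from the mean) of
#' pocket volumes per class label, as in a per-lineage cavity summary.
#'
#' @param class_labels character vector of class labels.
#' @param volumes numeric vector of volumes (A^3), parallel to
#'   `class_labels`; `metcof_pocket` objects are also accepted in a list.
#' @param digits rounding for the report columns (default 0, whole A^3).
#' @return data.frame with `class_label`, `n`, `mean_volume`,
#'   `average_deviation` (unrounded values in attributes `"mean"` and
#'   `"avgdev"`).
#' @export
aggregate_volumes <- function(class_labels, volumes, digits = 0) {
  if (is.list(volumes))
    volumes <- vapply(volumes, function(v) if (inherits(v, "metcof_pocket")) v$volume else as.numeric(v), 0)
  stopifnot(length(class_labels) == length(volumes), length(volumes) >= 1)
  cls <- unique(class_labels)
  mu <- vapply(cls, function(cl) mean(volumes[class_labels == cl]), 0)
  ad <- vapply(cls, function(cl) {
    v <- volumes[class_labels == cl]
    mean(abs(v - mean(v)))
  }, 0)
  out <- data.frame(
    class_label = cls,
    n = vapply(cls, function(cl) sum(class_labels == cl), 0L),
    mean_volume = round(mu, digits),
    average_deviation = round(ad, digits),
    stringsAsFactors = FALSE
  )
  attr(out, "mean") <- unname(mu)
  attr(out, "avgdev") <- unname(ad)
  rownames(out) <- NULL
  out
}
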