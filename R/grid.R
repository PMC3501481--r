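#' Synthetic MNI-like sampling grid
#'
#' Builds an isotropic voxel grid whose axis-aligned affine spans the usual
#' MNI bounding box (x in \[-90, 90\], y in \[-126, 90\], z in \[-72, 108\] mm),
#' so that literature seed coordinates land inside the volume.  The affine
#' maps 0-based voxel indices to mm.
#'
#' @param voxel_mm isotropic voxel size in mm (default 6).
#' @return an object of class `dmn_grid` with fields `dims` (integer triple),
#'   `voxel_mm` (mm triple) and `affine` (4x4 voxel-to-mm matrix).
#' @export
dmn_grid <- function(voxel_mm = 6) {
  stopifnot(is.numeric(voxel_mm), length(voxel_mm) == 1, voxel_mm > 0)
  span <- c(180, 216, 180)
  centre <- c(0, -18, 18)
  dims <- pmax(3L, as.integer(round(span / voxel_mm)))
  origin <- centre - (dims - 1) * voxel_mm / 2
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- origin
  structure(list(dims = dims, voxel_mm = rep(voxel_mm, 3), affine = affine),
            class = "dmn_grid")
}

#' Convert 0-based voxel indices to mm coordinates
#'
#' @param affine 4x4 voxel-to-mm matrix.
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
vox_to_mm <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  sweep(ijk %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}

#' Convert mm coordinates to (fractional) 0-based voxel indices
#' @inheritParams vox_to_mm
#' @param mm n x 3 matrix (or length-3 vector) of mm coordinates.
#' @export
mm_to_vox <- function(affine, mm) {
  mm <- matrix(mm, ncol = 3)
  sweep(mm, 2, affine[1:3, 4], `-`) %*% t(solve(affine[1:3, 1:3]))
}

# mm coordinates of every voxel centre, rows in array (column-major) order
voxel_centres <- function(grid) {
  d <- grid$dims
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  vox_to_mm(grid$affine, ijk)
}

#' Ellipsoidal brain mask for a synthetic grid
#'
#' A smooth stand-in for a template brain mask: an ellipsoid with semi-axes
#' (80, 104, 88) mm centred at (0, -18, 18), roughly the MNI brain envelope.
#'
#' @param grid a [dmn_grid()].
#' @return logical 3D array of the grid's dimensions.
#' @export
brain_mask <- function(grid) {
  mm <- voxel_centres(grid)
  r2 <- (mm[, 1] / 80)^2 + ((mm[, 2] + 18) / 104)^2 + ((mm[, 3] - 18) / 88)^2
  array(r2 <= 1, dim = grid$dims)
}

#' Spherical mask around an mm coordinate
#'
#' @param grid a [dmn_grid()].
#' @param centre_mm length-3 mm coordinate.
#' @param radius_mm sphere radius in mm (> 0); voxels whose centre lies
#'   within `radius_mm` of `centre_mm` are included.
#' @return logical 3D array.
#' @export
sphere_mask <- function(grid, centre_mm, radius_mm) {
  stopifnot(radius_mm > 0, length(centre_mm) == 3)
  mm <- voxel_centres(grid)
  d2 <- (mm[, 1] - centre_mm[1])^2 + (mm[, 2] - centre_mm[2])^2 +
    (mm[, 3] - centre_mm[3])^2
  array(d2 <= radius_mm^2, dim = grid$dims)
}

#' Template-style tissue masks for a synthetic grid
#'
#' Crude gray-matter / white-matter / CSF / whole-brain masks as concentric
#' ellipsoid shells, standing in for template anatomical masks.  The shells
#' deliberately do not tile the brain mask exactly (a rim is left
#' unassigned) so the whole-brain mean is not an exact linear combination
#' of the tissue means, as with real template masks.
#'
#' @param grid a [dmn_grid()].
#' @return named list of logical arrays: `gm`, `wm`, `csf`, `brain`.
#' @export
tissue_masks <- function(grid) {
  mm <- voxel_centres(grid)
  r2 <- (mm[, 1] / 80)^2 + ((mm[, 2] + 18) / 104)^2 + ((mm[, 3] - 18) / 88)^2
  brain <- r2 <= 1
  gm <- r2 <= 0.9 & r2 > 0.55
  wm <- r2 <= 0.55 & r2 > 0.15
  csf <- r2 <= 0.15
  lapply(list(gm = gm, wm = wm, csf = csf, brain = brain),
         function(m) array(m, dim = grid$dims))
}
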