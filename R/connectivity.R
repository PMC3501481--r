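#' The three canonical task-deactivation seed regions
#'
#' MPFC (-1, 47, -4), PCC/precuneus (-5, -49, 40) and left angular gyrus
#' (-45, -67, 36), in MNI mm; the three regions most consistently
#' deactivated across tasks in meta-analyses of the default mode network.
#'
#' @param radius_mm seed sphere radius in mm (default 6).
#' @return named list of seed specs (`name`, `center_mni`, `radius`).
#' @export
default_seeds <- function(radius_mm = 6) {
  stopifnot(radius_mm > 0)
  mk <- function(name, xyz) list(name = name, center_mni = xyz,
                                 radius = radius_mm)
  list(MPFC = mk("MPFC", c(-1, 47, -4)),
       PCC = mk("PCC", c(-5, -49, 40)),
       AG = mk("AG", c(-45, -67, 36)))
}

#' Fisher r-to-z transform
#'
#' z = atanh(r) with |r| clamped to `1 - clamp` so self-correlations stay
#' finite.
#'
#' @param r correlation value(s) in \[-1, 1\].
#' @param clamp clamping margin (default 1e-7).
#' @return z value(s).
#' @export
fisher_z <- function(r, clamp = 1e-7) {
  atanh(pmin(pmax(r, -1 + clamp), 1 - clamp))
}

#' Mean time course of a spherical seed
#'
#' Unweighted mean over in-mask voxels whose centres lie within the seed
#' radius of the seed centre (mm space via the series affine).
#'
#' @param series a voxel-mode `rest_series`.
#' @param seed a seed spec (see [default_seeds()]).
#' @return numeric vector of length n volumes.
#' @export
seed_timecourse <- function(series, seed) {
  stopifnot(inherits(series, "rest_series"), series$mode == "voxel")
  vox <- seed_voxels(series, seed)
  if (length(vox) == 0)
    stop("seed ", seed$name, " does not intersect the brain mask")
  Y <- series_matrix(series)
  rowMeans(Y[, vox, drop = FALSE])
}

# linear indices of in-mask voxels inside the seed sphere
seed_voxels <- function(series, seed) {
  d <- dim(series$data)[1:3]
  grid <- list(dims = d,
               voxel_mm = diag(series$affine)[1:3],
               affine = series$affine)
  sph <- sphere_mask(grid, seed$center_mni, seed$radius)
  keep <- if (!is.null(series$brain_mask)) sph & series$brain_mask else sph
  which(keep)
}

#' Seed-to-voxel connectivity map
#'
#' Pearson correlation of the seed's mean time course with every voxel,
#' plus the Fisher z map.  Zero-variance voxels get r = 0 and are flagged.
#'
#' @param series a voxel-mode `rest_series` with >= 10 volumes.
#' @param seed a seed spec.
#' @return list of class `connectivity_map`: `r_map` and `z_map` (3D
#'   arrays), `seed`, `n_timepoints`, `flagged` (zero-variance voxel
#'   indices).
#' @export
seed_map <- function(series, seed) {
  nt <- rest_n_volumes(series)
  if (nt < 10) stop("need >= 10 timepoints for a connectivity map")
  tc <- seed_timecourse(series, seed)
  Y <- series_matrix(series)
  r <- corr_with_vector(Y, tc)
  flagged <- which(is.na(r))
  r[flagged] <- 0
  d <- dim(series$data)[1:3]
  structure(list(r_map = array(r, d), z_map = array(fisher_z(r), d),
                 seed = seed, n_timepoints = nt, flagged = flagged),
            class = "connectivity_map")
}

# correlation of each column of Y (t x v) with vector x; NA for zero-variance
corr_with_vector <- function(Y, x) {
  xc <- x - mean(x)
  Yc <- sweep(Y, 2, colMeans(Y))
  num <- drop(crossprod(Yc, xc))
  den <- sqrt(colSums(Yc^2) * sum(xc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Average several connectivity maps voxelwise
#'
#' Arithmetic mean of the Fisher z maps (transform first, then average);
#' used to collapse the three seed maps into one DMN map per subject before
#' any group statistics.
#'
#' @param maps list of `connectivity_map`s on the same grid.
#' @return a `connectivity_map` whose `z_map` is the mean and whose `r_map`
#'   is its tanh back-transform; `seed$name` is "average".
#' @export
average_dmn_map <- function(maps) {
  stopifnot(length(maps) >= 1,
            all(vapply(maps, inherits, TRUE, "connectivity_map")))
  d <- dim(maps[[1]]$z_map)
  for (m in maps[-1])
    if (!identical(dim(m$z_map), d)) stop("grid mismatch between maps")
  z <- Reduce(`+`, lapply(maps, `[[`, "z_map")) / length(maps)
  structure(list(r_map = tanh(z), z_map = z,
                 seed = list(name = "average",
                             members = vapply(maps, function(m) m$seed$name, "")),
                 n_timepoints = maps[[1]]$n_timepoints,
                 flagged = sort(unique(unlist(lapply(maps, `[[`, "flagged"))))),
            class = "connectivity_map")
}

#' ROI-by-ROI Fisher z connectivity matrix
#'
#' Mean time course per atlas label (optionally with seed-sphere voxels
#' removed first), pairwise Pearson correlation, Fisher z.  ROI order is
#' fixed by sorted label id.  An ROI emptied by seed removal is excluded
#' with a warning.  For a roi-mode series (rows already ROI time courses)
#' pass `atlas = NULL`.
#'
#' @param series a `rest_series`.
#' @param atlas an atlas from [build_atlas()] (voxel mode) or NULL.
#' @param exclude integer label ids to drop (defaults to the atlas's own
#'   exclusion list).
#' @param seeds optional list of seed specs whose voxels are removed from
#'   the ROIs before computing time courses.
#' @return list of class `connectivity_matrix`: `roi_ids`, `roi_names`,
#'   `z_values` (symmetric, NA diagonal), `r_values`, `seed_excluded`
#'   (logical per ROI: lost voxels to a seed).
#' @export
roi_matrix <- function(series, atlas = NULL, exclude = NULL, seeds = NULL) {
  tc <- roi_timecourses(series, atlas, exclude, seeds)
  r <- stats::cor(tc$timecourses)
  zero_var <- which(apply(tc$timecourses, 2, stats::sd) == 0)
  if (length(zero_var)) r[zero_var, ] <- r[, zero_var] <- 0
  z <- fisher_z(r)
  diag(z) <- NA_real_
  diag(r) <- NA_real_
  structure(list(roi_ids = tc$roi_ids, roi_names = tc$roi_names,
                 z_values = z, r_values = r,
                 seed_excluded = tc$seed_excluded),
            class = "connectivity_matrix")
}

# volumes x roi matrix of mean ROI time courses
roi_timecourses <- function(series, atlas = NULL, exclude = NULL,
                            seeds = NULL) {
  stopifnot(inherits(series, "rest_series"))
  if (is.null(atlas)) {
    if (series$mode != "roi")
      stop("voxel-mode series needs an atlas")
    tcs <- t(series$data)
    ids <- seq_len(ncol(tcs))
    nms <- rownames(series$data) %||% paste0("ROI_", ids)
    return(list(timecourses = tcs, roi_ids = ids, roi_names = nms,
                seed_excluded = rep(FALSE, length(ids))))
  }
  if (!identical(dim(atlas$labels), dim(series$data)[1:3]))
    stop("atlas grid does not match series grid")
  if (is.null(exclude)) exclude <- atlas$exclude
  lab <- as.vector(atlas$labels)
  seed_vox <- integer(0)
  if (!is.null(seeds))
    seed_vox <- unique(unlist(lapply(seeds, function(s)
      seed_voxels(series, s))))
  ids <- sort(setdiff(unique(lab[lab > 0]), exclude))
  Y <- series_matrix(series)
  tcs <- matrix(NA_real_, nrow(Y), length(ids))
  seed_excluded <- logical(length(ids))
  keep_roi <- rep(TRUE, length(ids))
  for (i in seq_along(ids)) {
    vox <- which(lab == ids[i])
    vox2 <- setdiff(vox, seed_vox)
    seed_excluded[i] <- length(vox2) < length(vox)
    if (length(vox2) == 0) {
      warning("ROI ", ids[i], " emptied by seed removal; excluded")
      keep_roi[i] <- FALSE
      next
    }
    tcs[, i] <- rowMeans(Y[, vox2, drop = FALSE])
  }
  ids <- ids[keep_roi]
  list(timecourses = tcs[, keep_roi, drop = FALSE],
       roi_ids = ids,
       roi_names = atlas$table$name[match(ids, atlas$table$id)],
       seed_excluded = seed_excluded[keep_roi])
}

#' Seed-to-ROI connectivity feature vector
#'
#' Fisher z correlation between a seed's mean time course and every ROI's
#' mean time course (seed voxels removed from the ROIs first).
#'
#' @inheritParams roi_matrix
#' @param seed one seed spec.
#' @return named numeric z vector, one entry per retained ROI.
#' @export
seed_to_roi_vector <- function(series, seed, atlas = NULL, exclude = NULL) {
  tc <- roi_timecourses(series, atlas, exclude, seeds = list(seed))
  stc <- if (series$mode == "voxel") seed_timecourse(series, seed)
  else stop("seed-to-roi features need a voxel-mode series")
  r <- corr_with_vector(tc$timecourses, stc)
  r[is.na(r)] <- 0
  z <- fisher_z(r)
  names(z) <- tc$roi_names
  z
}

#' Upper-triangle feature vector of a connectivity matrix
#'
#' @param cm a `connectivity_matrix`.
#' @return named numeric vector of the strictly-upper-triangle z values,
#'   names "roiA--roiB".
#' @export
matrix_features <- function(cm) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  ut <- upper.tri(cm$z_values)
  idx <- which(ut, arr.ind = TRUE)
  v <- cm$z_values[ut]
  names(v) <- paste0(cm$roi_names[idx[, 1]], "--", cm$roi_names[idx[, 2]])
  v
}
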