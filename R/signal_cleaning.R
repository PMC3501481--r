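# time-by-feature matrix view of a rest series (features = voxels or ROIs)
series_matrix <- function(series) {
  d <- dim(series$data)
  if (length(d) == 2) t(series$data)
  else t(matrix(series$data, prod(d[1:3]), d[4]))
}

# write a time-by-feature matrix back into the series' native layout
series_restore <- function(series, Y) {
  d <- dim(series$data)
  out <- series
  if (length(d) == 2) {
    m <- t(Y)
    rownames(m) <- rownames(series$data)
    out$data <- m
  } else {
    out$data <- array(t(Y), dim = d)
  }
  out
}

#' Build the nuisance regressor matrix for a rest series
#'
#' Columns: six rigid-body motion parameters, one mean-motion column
#' (per-volume RMS of the six, centred), mean signal of each supplied tissue
#' mask (typically gray matter, white matter, CSF and whole brain), and a
#' per-session intercept plus linear trend (one pair per concatenated
#' segment-source run boundary: trends are fit within session, never across).
#' In roi mode (no masks) a single global column, the mean across ROIs,
#' stands in for the tissue means.
#'
#' @param series a `rest_series`.
#' @param motion volumes x 6 motion table aligned to the retained volumes;
#'   defaults to the motion carried by the series.
#' @param masks named list of logical arrays (e.g. gm/wm/csf/brain) on the
#'   series grid; NULL in roi mode.
#' @return list of class `nuisance_set`: `regressors` (volumes x k),
#'   `labels`, and `constant_flags` marking retained constant columns.
#' @export
build_nuisance <- function(series, motion = series$motion, masks = NULL) {
  stopifnot(inherits(series, "rest_series"))
  nt <- rest_n_volumes(series)
  cols <- list()
  labels <- character(0)

  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nt)
      stop("motion table has ", nrow(motion), " rows but series has ", nt,
           " volumes (misaligned)")
    if (ncol(motion) != 6) stop("motion table must have 6 columns")
    cols <- c(cols, lapply(seq_len(6), function(j) motion[, j]))
    labels <- c(labels, paste0("motion", 1:6))
    rms <- sqrt(rowMeans(motion^2))
    cols <- c(cols, list(rms - mean(rms)))
    labels <- c(labels, "mean_motion")
  }

  if (!is.null(masks)) {
    Y <- series_matrix(series)
    for (nm in names(masks)) {
      keep <- as.vector(masks[[nm]])
      if (!any(keep)) stop("empty ", nm, " mask")
      cols <- c(cols, list(rowMeans(Y[, keep, drop = FALSE])))
      labels <- c(labels, paste0(nm, "_mean"))
    }
  } else if (series$mode == "roi") {
    cols <- c(cols, list(colMeans(series$data)))
    labels <- c(labels, "global_mean")
  }

  seg <- segment_index_by_run(series)
  for (s in unique(seg)) {
    inside <- seg == s
    ic <- as.numeric(inside)
    tc <- numeric(nt)
    tt <- seq_len(sum(inside)) - (sum(inside) + 1) / 2
    tc[inside] <- tt / max(abs(tt), 1)
    cols <- c(cols, list(ic, tc))
    labels <- c(labels, paste0("intercept_", s), paste0("trend_", s))
  }

  X <- do.call(cbind, cols)
  colnames(X) <- labels
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  structure(list(regressors = X, labels = labels, constant_flags = const),
            class = "nuisance_set")
}

# per-volume source-run index; trends/intercepts are per original session
segment_index_by_run <- function(series) {
  rep(match(series$segments$run, unique(series$segments$run)),
      series$segments$n)
}

#' Regress nuisance signals out of a rest series
#'
#' Ordinary least squares projection: residuals are orthogonal to every
#' regressor, per feature variance is never increased.  A rank-deficient
#' nuisance matrix is handled by the pivoted QR (pseudo-inverse solution)
#' with a warning.
#'
#' @param series a `rest_series`.
#' @param nuisance a `nuisance_set` from [build_nuisance()].
#' @return the residual `rest_series`.
#' @export
regress_out <- function(series, nuisance) {
  stopifnot(inherits(series, "rest_series"), inherits(nuisance, "nuisance_set"))
  X <- nuisance$regressors
  nt <- rest_n_volumes(series)
  if (nrow(X) != nt) stop("nuisance rows do not match series volumes")
  qx <- qr(X)
  if (qx$rank < ncol(X))
    warning("nuisance matrix is rank deficient (rank ", qx$rank, " of ",
            ncol(X), "); using pseudo-inverse solution")
  Y <- series_matrix(series)
  series_restore(series, qr.resid(qx, Y))
}

#' Spatial Gaussian smoothing of a volume (series)
#'
#' Separable per-axis Gaussian convolution with sigma = FWHM / (2 sqrt(2
#' ln 2)) in mm, converted per axis by the voxel size.  Boundary handling is
#' symmetric reflection, which preserves total mass for interior signal.
#'
#' @param data 3D array or 4D array (smoothed volume-by-volume).
#' @param fwhm full width at half maximum in mm (>= 0; 0 is the identity).
#' @param voxel_mm voxel size, scalar or mm triple (anisotropic handled
#'   per axis).
#' @return array of the same shape.
#' @export
smooth_gaussian <- function(data, fwhm, voxel_mm) {
  if (fwhm < 0) stop("fwhm must be >= 0")
  if (fwhm == 0) return(data)
  voxel_mm <- rep(as.numeric(voxel_mm), length.out = 3)
  sigma_vox <- (fwhm / (2 * sqrt(2 * log(2)))) / voxel_mm
  nd <- length(dim(data))
  stopifnot(nd %in% c(3, 4))
  for (ax in 1:3) data <- conv_axis_gauss(data, ax, sigma_vox[ax])
  data
}

# Gaussian convolution along one axis with reflect boundary
conv_axis_gauss <- function(data, axis, sigma) {
  if (sigma <= 0) return(data)
  rad <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  d <- dim(data)
  perm <- c(axis, setdiff(seq_along(d), axis))
  x <- aperm(data, perm)
  dp <- dim(x)
  n <- dp[1]
  xm <- matrix(x, n)
  out <- matrix(0, n, ncol(xm))
  base <- seq_len(n)
  for (j in seq_along(k)) {
    idx <- base + (j - rad - 1L)
    idx <- ifelse(idx < 1L, 1L - idx, idx)          # reflect low edge
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)  # reflect high edge
    out <- out + k[j] * xm[idx, , drop = FALSE]
  }
  aperm(array(out, dp), order(perm))
}
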