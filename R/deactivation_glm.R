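#' Build a task GLM design matrix for a blocked run
#'
#' One HRF-convolved boxcar per condition (optionally with conditions
#' collapsed into groups such as "language"), plus an intercept.  Modelling
#' the rest blocks explicitly is optional: in designs whose blocks tile the
#' whole run, rest + task boxcars + intercept are collinear, so the default
#' treats rest as the implicit baseline and deactivation is read from the
#' negated task coefficients.
#'
#' @param design a [session_design()].
#' @param collapse optional named list mapping regressor-group name ->
#'   character vector of condition labels (e.g. `list(language = c("pun",
#'   "literal"))`).  Conditions not mentioned keep their own column.
#' @param include_rest model the rest blocks as their own regressor
#'   (default FALSE: rest is the baseline).
#' @return list of class `design_matrix` with `columns` (volumes x k),
#'   `condition_names` and `hrf_model = "double-gamma"`.
#' @export
build_design_matrix <- function(design, collapse = NULL, include_rest = FALSE) {
  stopifnot(inherits(design, "session_design"))
  conds <- unique(design$blocks$condition)
  task_conds <- setdiff(conds, "rest")
  groups <- list()
  if (!is.null(collapse)) {
    unknown <- setdiff(unlist(collapse), conds)
    if (length(unknown))
      stop("unknown condition label(s): ", paste(unknown, collapse = ", "))
    groups <- collapse
    leftover <- setdiff(task_conds, unlist(collapse))
  } else {
    leftover <- task_conds
  }
  for (cn in leftover) groups[[cn]] <- cn
  if (include_rest) groups[["rest"]] <- "rest"

  nv <- design$acquisition$n_volumes
  cols <- vapply(groups, function(g) condition_regressor(design, g),
                 numeric(nv))
  cols <- cbind(intercept = rep(1, nv), cols)
  structure(list(columns = cols,
                 condition_names = names(groups),
                 hrf_model = "double-gamma"),
            class = "design_matrix")
}

#' Fit a mass-univariate GLM and compute a contrast t map
#'
#' Per-feature (voxel or ROI) ordinary least squares on the design columns,
#' with the t statistic for the given contrast and df = volumes - rank(X).
#' Collinear columns are dropped with a warning; a contrast touching a
#' dropped column is an error.
#'
#' @param Y volumes x features matrix, a `rest_series`, or a [bold_run()].
#' @param X a `design_matrix` (or plain matrix with column names).
#' @param contrast named numeric vector of weights over design columns;
#'   unnamed columns get weight 0.
#' @return list of class `stat_map`: `values` (t per feature), `effect`
#'   (contrast estimate per feature), `df`, `contrast`, and `shape` to
#'   restore voxel maps.
#' @export
fit_glm <- function(Y, X, contrast) {
  shape <- NULL
  if (inherits(Y, "rest_series")) {
    shape <- if (length(dim(Y$data)) == 4) dim(Y$data)[1:3]
    Y <- series_matrix(Y)
  } else if (inherits(Y, "bold_run")) {
    d <- dim(Y$data)
    if (length(d) == 4) {
      shape <- d[1:3]
      Y <- t(matrix(Y$data, prod(d[1:3]), d[4]))
    } else Y <- t(Y$data)
  }
  Xm <- if (inherits(X, "design_matrix")) X$columns else X
  if (nrow(Xm) != nrow(Y)) stop("design and data rows do not align")
  cw <- numeric(ncol(Xm))
  names(cw) <- colnames(Xm)
  bad <- setdiff(names(contrast), colnames(Xm))
  if (length(bad)) stop("contrast names not in design: ",
                        paste(bad, collapse = ", "))
  cw[names(contrast)] <- contrast

  qx <- qr(Xm)
  rank <- qx$rank
  keep <- qx$pivot[seq_len(rank)]
  if (rank < ncol(Xm)) {
    dropped <- colnames(Xm)[qx$pivot[-seq_len(rank)]]
    warning("dropping collinear design column(s): ",
            paste(dropped, collapse = ", "))
    if (any(cw[dropped] != 0))
      stop("contrast involves dropped column(s): ",
           paste(intersect(names(contrast), dropped), collapse = ", "))
    Xm <- Xm[, keep, drop = FALSE]
    cw <- cw[keep]
    qx <- qr(Xm)
  }
  beta <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  df <- nrow(Y) - rank
  sigma2 <- colSums(res^2) / df
  # with pivoting X P = QR, (X'X)^{-1} = P (R'R)^{-1} P'
  inv_perm <- order(qx$pivot)
  XtXinv <- chol2inv(qr.R(qx))[inv_perm, inv_perm, drop = FALSE]
  cvar <- drop(t(cw) %*% XtXinv %*% cw)
  eff <- drop(cw %*% beta)
  tval <- eff / sqrt(pmax(cvar * sigma2, .Machine$double.eps))
  tval[sigma2 == 0 & eff == 0] <- 0
  structure(list(values = tval, effect = eff, df = df,
                 contrast = cw, shape = shape),
            class = "stat_map")
}

#' Voxelwise one- or two-sample t test across subjects
#'
#' Random-effects style group inference on subject-level maps: a matrix of
#' subjects x features, with `groups` splitting rows into two groups for a
#' pooled-variance two-sample t (first level minus second), or NULL for a
#' one-sample t against zero.
#'
#' @param maps subjects x features numeric matrix (or list of equal-length
#'   vectors, one per subject).
#' @param groups optional factor/character of length nrow(maps) with
#'   exactly two levels; each group needs >= 2 subjects.
#' @return list of class `stat_map` with `values` (t), `df`, `p`
#'   (two-sided).
#' @export
group_ttest <- function(maps, groups = NULL) {
  if (is.list(maps)) maps <- do.call(rbind, maps)
  maps <- as.matrix(maps)
  if (is.null(groups)) {
    n <- nrow(maps)
    if (n < 2) stop("need >= 2 subjects")
    m <- colMeans(maps)
    se <- sqrt(apply(maps, 2, stats::var) / n)
    tv <- m / se
    tv[se == 0 & m == 0] <- 0
    df <- n - 1
  } else {
    groups <- as.factor(groups)
    if (nlevels(groups) != 2) stop("groups must have exactly two levels")
    a <- maps[groups == levels(groups)[1], , drop = FALSE]
    b <- maps[groups == levels(groups)[2], , drop = FALSE]
    n1 <- nrow(a); n2 <- nrow(b)
    if (min(n1, n2) < 2) stop("each group needs >= 2 subjects")
    sp2 <- ((n1 - 1) * apply(a, 2, stats::var) +
              (n2 - 1) * apply(b, 2, stats::var)) / (n1 + n2 - 2)
    diff <- colMeans(a) - colMeans(b)
    tv <- diff / sqrt(sp2 * (1 / n1 + 1 / n2))
    tv[sp2 == 0 & diff == 0] <- 0  # identical groups: no evidence, t = 0
    df <- n1 + n2 - 2
  }
  p <- 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
  structure(list(values = tv, df = df, p = p, shape = NULL),
            class = "stat_map")
}

#' Benjamini-Hochberg FDR threshold
#'
#' Step-up procedure: with m ordered p-values, reject all p(i) up to the
#' largest i with p(i) <= q * i / m.
#'
#' @param p_values numeric vector in \[0, 1\] (NAs not allowed).
#' @param q target false discovery rate (default 0.05).
#' @return logical rejection vector aligned to `p_values`; attribute
#'   `p_threshold` carries the realised cutoff (0 when nothing is rejected).
#' @export
fdr_threshold <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  stopifnot(all(p_values >= 0 & p_values <= 1), q > 0)
  m <- length(p_values)
  o <- order(p_values)
  ps <- p_values[o]
  below <- which(ps <= q * seq_len(m) / m)
  cut <- if (length(below)) ps[max(below)] else -1
  out <- p_values <= cut
  attr(out, "p_threshold") <- max(cut, 0)
  out
}

# neighbour offsets for 6/18/26 connectivity
neighbour_offsets <- function(connectivity = 18) {
  stopifnot(connectivity %in% c(6, 18, 26))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1,
                 "18" = nz >= 1 & rowSums(g != 0) <= 2,
                 "26" = nz >= 1)
  g[keep, , drop = FALSE]
}

# connected components over the TRUE voxels of a logical 3D array.
# Returns a list of integer vectors of linear voxel indices, one per
# component; independent of voxel visit order by construction.
connected_components <- function(mask, connectivity = 18) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(list())
  lab <- array(0L, d)
  offs <- neighbour_offsets(connectivity)
  comps <- list()
  for (seed in idx) {
    if (lab[seed] != 0L) next
    comp_id <- length(comps) + 1L
    stack <- seed
    lab[seed] <- comp_id
    members <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, v)
      k0 <- (v - 1L) %/% (d[1] * d[2])
      j0 <- ((v - 1L) %/% d[1]) %% d[2]
      i0 <- (v - 1L) %% d[1]
      ni <- i0 + offs[, 1]; nj <- j0 + offs[, 2]; nk <- k0 + offs[, 3]
      ok <- ni >= 0 & ni < d[1] & nj >= 0 & nj < d[2] & nk >= 0 & nk < d[3]
      nv <- 1L + ni[ok] + d[1] * (nj[ok] + d[2] * nk[ok])
      nv <- nv[mask[nv] & lab[nv] == 0L]
      if (length(nv)) {
        lab[nv] <- comp_id
        stack <- c(stack, nv)
      }
    }
    comps[[comp_id]] <- sort(members)
  }
  comps
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates Gaussian noise inside the mask, optionally smooths it to the
#' stated FWHM (then re-standardises to unit variance in-mask), thresholds
#' two-sided at `voxel_p`, and records the maximum suprathreshold cluster
#' size per simulation.  The returned extent `k_min` is the smallest k for
#' which P(max cluster >= k) <= alpha, i.e. requiring clusters of at least
#' `k_min` voxels controls the family-wise error at `alpha`.
#'
#' @param mask logical 3D array (non-empty).
#' @param smoothness_fwhm residual smoothness FWHM in mm (0 = independent
#'   voxels).
#' @param voxel_p two-sided voxelwise p threshold, in (0, 1).
#' @param n_sim number of simulations (default 10000; < 100 warns).
#' @param alpha family-wise error target (>= 1 short-circuits to k = 1).
#' @param connectivity 6, 18 or 26 (default 18).
#' @param voxel_mm voxel size in mm (scalar or triple), used to convert the
#'   FWHM.
#' @param seed RNG seed for reproducibility.
#' @return integer `k_min`; attribute `max_sizes` carries the simulated
#'   maxima.
#' @export
cluster_extent_threshold <- function(mask, smoothness_fwhm = 0,
                                     voxel_p = 0.001, n_sim = 10000,
                                     alpha = 0.05, connectivity = 18,
                                     voxel_mm = 3, seed = 1) {
  stopifnot(any(mask), voxel_p > 0, voxel_p < 1)
  if (alpha >= 1) return(1L)
  if (n_sim < 100) warning("n_sim < 100 gives an unstable extent threshold")
  d <- dim(mask)
  inmask <- which(mask)
  zcrit <- stats::qnorm(1 - voxel_p / 2)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  max_sizes <- integer(n_sim)
  for (s in seq_len(n_sim)) {
    noise <- array(stats::rnorm(prod(d)), d)
    if (smoothness_fwhm > 0) {
      noise <- smooth_gaussian(noise, smoothness_fwhm, voxel_mm)
      noise <- noise / stats::sd(noise[inmask])
    }
    supra <- array(FALSE, d)
    supra[inmask] <- abs(noise[inmask]) >= zcrit
    if (!any(supra)) next
    comps <- connected_components(supra, connectivity)
    max_sizes[s] <- max(lengths(comps))
  }
  # smallest k with tail probability <= alpha
  for (k in seq_len(max(max_sizes) + 1L)) {
    if (mean(max_sizes >= k) <= alpha) break
  }
  structure(as.integer(k), max_sizes = max_sizes)
}

#' Extract suprathreshold clusters from a stat map
#'
#' Thresholds the map, finds connected components, and keeps those of at
#' least `k_min` voxels.  Peak coordinates are reported in mm through the
#' affine.
#'
#' @param values 3D array of statistic values (or a `stat_map` carrying a
#'   `shape`).
#' @param stat_threshold threshold on the statistic (> 0).
#' @param k_min minimum cluster extent in voxels.
#' @param connectivity 6, 18 or 26 (default 18).
#' @param affine optional 4x4 voxel-to-mm matrix for peak coordinates.
#' @param direction "greater" keeps values >= threshold, "less" keeps
#'   values <= -threshold, "two.sided" thresholds on |value| (default
#'   "greater").
#' @return data.frame with one row per cluster: `k`, `peak_x/y/z` (mm when
#'   an affine is given, else 0-based voxel indices), `peak_stat`; ordered
#'   by decreasing size.  Empty data.frame when nothing survives.
#' @export
extract_clusters <- function(values, stat_threshold, k_min = 1,
                             connectivity = 18, affine = NULL,
                             direction = c("greater", "less", "two.sided")) {
  direction <- match.arg(direction)
  stopifnot(stat_threshold > 0, k_min >= 1)
  if (inherits(values, "stat_map")) {
    if (is.null(values$shape)) stop("stat_map carries no voxel shape")
    values <- array(values$values, values$shape)
  }
  d <- dim(values)
  stopifnot(length(d) == 3)
  supra <- switch(direction,
                  greater = values >= stat_threshold,
                  less = values <= -stat_threshold,
                  two.sided = abs(values) >= stat_threshold)
  supra[is.na(supra)] <- FALSE
  comps <- connected_components(supra, connectivity)
  comps <- comps[lengths(comps) >= k_min]
  if (length(comps) == 0)
    return(data.frame(k = integer(0), peak_x = numeric(0),
                      peak_y = numeric(0), peak_z = numeric(0),
                      peak_stat = numeric(0)))
  rows <- lapply(comps, function(vox) {
    vals <- values[vox]
    pk <- vox[which.max(abs(vals))]
    ijk <- c((pk - 1) %% d[1],
             ((pk - 1) %/% d[1]) %% d[2],
             (pk - 1) %/% (d[1] * d[2]))
    mm <- if (!is.null(affine)) drop(vox_to_mm(affine, ijk)) else ijk
    data.frame(k = length(vox), peak_x = mm[1], peak_y = mm[2],
               peak_z = mm[3], peak_stat = values[pk])
  })
  out <- do.call(rbind, rows)
  out[order(-out$k), , drop = FALSE]
}
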