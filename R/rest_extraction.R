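#' Construct a BOLD run
#'
#' Container for one run's data and metadata.  `data` is either a 4D array
#' (x, y, z, t) of voxel values or a 2D matrix (roi, t) of region time
#' courses; the time dimension must match the design's volume count.
#'
#' @param data 4D array or roi-by-time matrix.
#' @param design the run's [session_design()].
#' @param affine 4x4 voxel-to-mm matrix (voxel mode).
#' @param brain_mask logical 3D array matching the spatial dims (voxel mode).
#' @param motion optional volumes x 6 motion-parameter matrix.
#' @param roi_names optional row labels (roi mode).
#' @return list of class `bold_run`.
#' @export
bold_run <- function(data, design, affine = NULL, brain_mask = NULL,
                     motion = NULL, roi_names = NULL) {
  stopifnot(inherits(design, "session_design"))
  nd <- length(dim(data))
  if (!nd %in% c(2, 4)) stop("data must be a 2D (roi,t) or 4D (x,y,z,t) array")
  nt <- if (nd == 2) ncol(data) else dim(data)[4]
  if (nt != design$acquisition$n_volumes)
    stop("time dimension (", nt, ") does not match design n_volumes (",
         design$acquisition$n_volumes, ")")
  if (nd == 4 && !is.null(brain_mask) &&
      !identical(dim(brain_mask), dim(data)[1:3]))
    stop("brain_mask shape does not match data")
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nt)
      stop("motion table rows (", nrow(motion), ") != volumes (", nt, ")")
  }
  if (nd == 2 && !is.null(roi_names)) rownames(data) <- roi_names
  structure(list(data = data, design = design, affine = affine,
                 brain_mask = brain_mask, motion = motion,
                 mode = if (nd == 2) "roi" else "voxel"),
            class = "bold_run")
}

n_timepoints <- function(x) {
  d <- dim(x$data)
  if (length(d) == 2) d[2] else d[4]
}

time_subset <- function(data, idx) {
  if (length(dim(data)) == 2) data[, idx, drop = FALSE]
  else data[, , , idx, drop = FALSE]
}

#' Excise rest blocks into a pseudo-resting-state series
#'
#' Removes task blocks and, from every rest block, the first `lag` seconds
#' (hemodynamic return to baseline).  When all of a run's rest blocks are
#' shorter than `append_threshold` seconds, the first `lag` seconds of the
#' immediately following task block are appended to each rest segment to
#' compensate (hemodynamic delay carries rest-like signal into early task
#' volumes).  Retained segments are concatenated in temporal order, with
#' full provenance kept in `segments`.
#'
#' Seconds are converted to 0-based, half-open volume windows; a volume is
#' retained only if it lies wholly inside the retained interval.
#'
#' @param run a [bold_run()].
#' @param lag seconds trimmed from the head of every rest block (default 6).
#' @param append_threshold rest-block duration (s) below which the task
#'   appendage rule applies (default 20, i.e. 15-s rest designs).
#' @return list of class `rest_series` with fields `data`, `tr`, `segments`
#'   (data.frame: block, source_start, source_end, n), `retained` (0-based
#'   source volume indices), plus carried-over `affine`, `brain_mask`,
#'   `motion` and `mode`.
#' @export
excise_rest_blocks <- function(run, lag = 6, append_threshold = 20) {
  stopifnot(inherits(run, "bold_run"), lag >= 0)
  b <- run$design$blocks
  tr <- run$design$acquisition$tr
  rest <- which(b$condition == "rest")
  if (length(rest) == 0) stop("design has no rest blocks")
  if (any(b$duration[rest] <= lag))
    stop("rest block of ", min(b$duration[rest]),
         " s is not longer than the ", lag, " s lag")
  append_task <- all(b$duration[rest] < append_threshold)

  seg <- list()
  for (i in rest) {
    v0 <- ceiling((b$onset[i] + lag) / tr - 1e-9)
    v1 <- floor((b$onset[i] + b$duration[i]) / tr + 1e-9)
    idx <- if (v1 > v0) v0:(v1 - 1) else integer(0)
    if (append_task) {
      j <- if (i < nrow(b)) i + 1L else NA_integer_
      if (!is.na(j) && b$condition[j] != "rest") {
        t0 <- ceiling(b$onset[j] / tr - 1e-9)
        t1 <- floor((b$onset[j] + lag) / tr + 1e-9)
        if (t1 > t0) idx <- c(idx, t0:(t1 - 1))
      } else {
        warning("rest block ", i, " has no following task block; ",
                "segment retained without appendage")
      }
    }
    if (length(idx))
      seg[[length(seg) + 1]] <- data.frame(block = i,
                                           source_start = idx[1],
                                           source_end = idx[length(idx)] + 1L,
                                           n = length(idx))
  }
  segments <- do.call(rbind, seg)
  segments$run <- run$design$study_id
  retained <- unlist(lapply(seg, function(s) s$source_start:(s$source_end - 1L)))
  structure(list(
    data = time_subset(run$data, retained + 1L),
    tr = tr,
    segments = segments[, c("run", "block", "source_start", "source_end", "n")],
    retained = retained,
    affine = run$affine, brain_mask = run$brain_mask,
    motion = if (!is.null(run$motion)) run$motion[retained + 1L, , drop = FALSE],
    mode = run$mode), class = "rest_series")
}

#' @export
print.rest_series <- function(x, ...) {
  cat("rest_series: ", rest_n_volumes(x), " volumes in ",
      nrow(x$segments), " segments @ TR ", x$tr, " s\n", sep = "")
  invisible(x)
}

#' Number of volumes in a rest series
#' @param series a `rest_series`.
#' @export
rest_n_volumes <- function(series) {
  d <- dim(series$data)
  if (length(d) == 2) d[2] else d[4]
}

#' Concatenate rest series across runs
#'
#' Joins per-run pseudo-resting-state series in the given order, preserving
#' per-segment provenance (so later detrending can stay within session).
#' No temporal filtering happens across boundaries.
#'
#' @param series list of `rest_series` sharing spatial shape and TR.
#' @return a single `rest_series`.
#' @export
concatenate_runs <- function(series) {
  stopifnot(length(series) >= 1,
            all(vapply(series, inherits, TRUE, "rest_series")))
  if (length(series) == 1) return(series[[1]])
  d1 <- dim(series[[1]]$data)
  sp <- d1[-length(d1)]
  for (s in series[-1]) {
    ds <- dim(s$data)
    if (!identical(ds[-length(ds)], sp))
      stop("spatial shape mismatch between runs")
    if (!isTRUE(all.equal(s$tr, series[[1]]$tr)))
      stop("TR mismatch between runs")
  }
  nts <- vapply(series, rest_n_volumes, 1L)
  data <- array(unlist(lapply(series, function(s) s$data), use.names = FALSE),
                dim = c(sp, sum(nts)))
  if (length(sp) == 1) {  # roi mode: keep matrix class and row names
    data <- matrix(data, nrow = sp, ncol = sum(nts))
    rownames(data) <- rownames(series[[1]]$data)
  }
  segments <- do.call(rbind, lapply(series, function(s) s$segments))
  rownames(segments) <- NULL
  motion <- lapply(series, function(s) s$motion)
  motion <- if (all(!vapply(motion, is.null, TRUE))) do.call(rbind, motion)
  structure(list(data = data, tr = series[[1]]$tr, segments = segments,
                 retained = NULL,
                 affine = series[[1]]$affine,
                 brain_mask = series[[1]]$brain_mask,
                 motion = motion, mode = series[[1]]$mode),
            class = "rest_series")
}

# per-volume segment index (1..n_segments) for a concatenated series
segment_index <- function(series) {
  rep(seq_len(nrow(series$segments)), series$segments$n)
}
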