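#' Default node set for the synthetic cohort
#'
#' Ten well-separated cortical nodes.  Five are default-mode nodes (`dmn =
#' TRUE`): MPFC, PCC/precuneus, left angular gyrus, right inferior parietal
#' lobule and left superior frontal gyrus; the rest are task-positive or
#' sensory controls.  Coordinates are MNI mm; the first three coincide with
#' the canonical deactivation seeds so seed spheres fall inside their nodes.
#'
#' @param radius_mm node sphere radius in mm (default 8).
#' @return data.frame (name, x, y, z, radius, dmn, anterior).
#' @export
default_nodes <- function(radius_mm = 8) {
  stopifnot(radius_mm > 0)
  df <- data.frame(
    name = c("MPFC", "PCC", "AG_L", "DLPFC_L", "DLPFC_R",
             "STG_R", "MTG_R", "IPL_R", "SFG_L", "V1_R"),
    x = c(-1, -5, -45, -42, 28, 66, 64, 48, -20, 10),
    y = c(47, -49, -67, 40, 30, -24, -20, -60, 46, -90),
    z = c(-4, 40, 36, 18, 48, 6, -18, 40, 44, 0),
    dmn = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    anterior = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE,
                 FALSE),
    stringsAsFactors = FALSE)
  df$radius <- radius_mm
  df
}

# nearest positive semi-definite correlation matrix: eigenvalue clipping
# followed by re-normalisation to unit diagonal
nearest_psd_corr <- function(m, eps = 1e-10) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values >= -eps)) {
    diag(m) <- 1
    return(m)
  }
  v <- pmax(e$values, 0)
  out <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(out))
  if (any(d <= 0)) stop("matrix cannot be repaired to a valid correlation")
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Cohort specification with a planted MPFC connectivity deficit
#'
#' Builds the two groups' target correlation matrices and deactivation
#' amplitudes.  The control-like group (`b`) has strong anterior-posterior
#' default-mode coupling (MPFC-PCC 0.6, PCC-AG 0.6, other within-DMN pairs
#' 0.5, background 0.1) and task deactivation of -1 BOLD unit in DMN nodes.
#' The clinical-like group (`a`) is identical except that the MPFC's
#' couplings to the other DMN nodes are reduced by `effect_size` (then
#' re-projected to the nearest positive semi-definite correlation matrix)
#' and its DMN deactivation is attenuated to -0.4.
#'
#' @param effect_size reduction of MPFC-DMN coupling, in \[0, 1).
#' @param seed integer RNG seed stored as `rng_seed`.
#' @param n_group_a,n_group_b group sizes (defaults 13 and 14).
#' @param nodes node table from [default_nodes()].
#' @param noise_sd,drift_slope,global_amp,motion_coupling nuisance component
#'   amplitudes (BOLD units; drift is units/volume).
#' @return list of class `cohort_spec`.
#' @export
make_dmn_cohort_spec <- function(effect_size = 0.3, seed = 42,
                                 n_group_a = 13, n_group_b = 14,
                                 nodes = default_nodes(),
                                 noise_sd = 0.5, drift_slope = 0.005,
                                 global_amp = 0.5, motion_coupling = 0.3) {
  stopifnot(effect_size >= 0, effect_size < 1,
            n_group_a >= 2, n_group_b >= 2)
  k <- nrow(nodes)
  corr_b <- matrix(0.1, k, k, dimnames = list(nodes$name, nodes$name))
  dmn <- which(nodes$dmn)
  corr_b[dmn, dmn] <- 0.5
  corr_b["MPFC", "PCC"] <- corr_b["PCC", "MPFC"] <- 0.6
  corr_b["PCC", "AG_L"] <- corr_b["AG_L", "PCC"] <- 0.6
  diag(corr_b) <- 1
  corr_b <- nearest_psd_corr(corr_b)

  corr_a <- corr_b
  others <- setdiff(dmn, which(nodes$name == "MPFC"))
  corr_a["MPFC", others] <- corr_a["MPFC", others] - effect_size
  corr_a[others, "MPFC"] <- corr_a["MPFC", others]
  corr_a <- nearest_psd_corr(corr_a)
  if (min(eigen(corr_a, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("effect_size leaves group-a matrix non-PSD after projection")

  amp_b <- ifelse(nodes$dmn, -1, 0)
  amp_a <- ifelse(nodes$dmn, -0.4, 0)
  names(amp_a) <- names(amp_b) <- nodes$name

  structure(list(n_group_a = n_group_a, n_group_b = n_group_b,
                 node_set = nodes, effect_size = effect_size,
                 corr_a = corr_a, corr_b = corr_b,
                 deact_amp_a = amp_a, deact_amp_b = amp_b,
                 noise_sd = noise_sd, drift_slope = drift_slope,
                 global_amp = global_amp, motion_coupling = motion_coupling,
                 rng_seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Synthetic labelled atlas on a grid
#'
#' Every node sphere becomes one ROI label (1..K); remaining brain voxels
#' are split, in (z, y, x) order, into equal-sized pseudo-ROI slabs so the
#' atlas carries `n_labels` labels in total.  The `n_exclude` pseudo-ROIs
#' with the lowest z (an inferior "cerebellum-like" band) form the default
#' exclusion list, emulating a 116-label parcellation reduced to 102
#' usable ROIs.  Shapes are synthetic; only the counts and the coordinate
#' conventions mimic a real anatomical parcellation.
#'
#' @param grid a [dmn_grid()].
#' @param nodes node table from [default_nodes()].
#' @param n_labels total label count (default 116).
#' @param n_exclude labels in the default exclusion list (default 14).
#' @return list of class `dmn_atlas`: `labels` (integer 3D array, 0 =
#'   background), `exclude` (label ids), `table` (id, name).
#' @export
build_atlas <- function(grid, nodes = default_nodes(), n_labels = 116,
                        n_exclude = 14) {
  k <- nrow(nodes)
  stopifnot(n_labels > k + n_exclude)
  lab <- array(0L, grid$dims)
  brain <- brain_mask(grid)
  for (i in seq_len(k)) {
    sph <- sphere_mask(grid, c(nodes$x[i], nodes$y[i], nodes$z[i]),
                       nodes$radius[i]) & brain
    if (!any(sph)) stop("node ", nodes$name[i], " is outside the grid/brain")
    if (any(lab[sph] != 0))
      stop("node ", nodes$name[i], " overlaps another node")
    lab[sph] <- i
  }
  rest <- which(brain & lab == 0L)
  mm <- voxel_centres(grid)[rest, , drop = FALSE]
  ord <- order(mm[, 3], mm[, 2], mm[, 1])
  n_pseudo <- n_labels - k
  chunk <- cut(seq_along(ord), breaks = n_pseudo, labels = FALSE)
  lab[rest[ord]] <- k + chunk
  pseudo_ids <- k + seq_len(n_pseudo)
  exclude <- pseudo_ids[seq_len(n_exclude)]  # lowest-z slabs
  table <- data.frame(
    id = c(seq_len(k), pseudo_ids),
    name = c(nodes$name, sprintf("ROI_%03d", pseudo_ids)),
    stringsAsFactors = FALSE)
  structure(list(labels = lab, exclude = exclude, table = table),
            class = "dmn_atlas")
}

# node time-series for one run: latent correlated rest signal + HRF task
# response + drift + motion-coupled + global + white noise.  Returns the
# node signals, the shared (background) component and the motion table.
simulate_run_signals <- function(spec, design, corr, amps) {
  a <- design$acquisition
  n <- a$n_volumes
  k <- nrow(spec$node_set)
  latent <- matrix(stats::rnorm(n * k), n, k) %*% chol(nearest_psd_corr(corr))
  task <- convolve_hrf(
    boxcar_regressor(design$blocks$onset[design$blocks$condition != "rest"],
                     design$blocks$duration[design$blocks$condition != "rest"],
                     n, a$tr), a$tr)
  motion <- matrix(stats::rnorm(n * 6, sd = 0.02), n, 6)
  motion <- apply(motion, 2, cumsum)
  drift <- spec$drift_slope * (seq_len(n) - (n + 1) / 2)
  global <- spec$global_amp * stats::rnorm(n)
  m1 <- motion[, 1]
  mc <- if (stats::sd(m1) > 0) spec$motion_coupling * (m1 - mean(m1)) / stats::sd(m1)
  else numeric(n)
  shared <- drift + global + mc
  node <- t(latent) + outer(amps[spec$node_set$name], task) +
    matrix(shared, k, n, byrow = TRUE)
  noise <- matrix(stats::rnorm(k * n, sd = spec$noise_sd), k, n)
  list(node = node + noise, shared = shared, motion = motion)
}

#' Generate one synthetic subject
#'
#' Runs are simulated from the subject's group parameters (see
#' [make_dmn_cohort_spec()]) for each design.  In "roi" mode each run's
#' data is the node-by-time matrix; in "voxel" mode node signals are
#' painted into their atlas spheres on the grid, all other brain voxels
#' receive the shared nuisance components plus white noise.  The per
#' subject/run RNG stream is derived deterministically from `spec$rng_seed`
#' so identical specs reproduce identical data.
#'
#' @param spec a `cohort_spec`.
#' @param subject_index 1-based index within the cohort (group a first).
#' @param designs list of [session_design()]s (default
#'   [canonical_designs()]).
#' @param mode "roi" or "voxel".
#' @param grid grid for voxel mode (default `dmn_grid(6)`).
#' @param atlas optional prebuilt [build_atlas()] matching `grid`.
#' @return list of class `synthetic_subject`: `subject_id`, `group` ("a" or
#'   "b"), `runs` (list of [bold_run()]), `truth` (group parameters).
#' @export
generate_subject <- function(spec, subject_index,
                             designs = canonical_designs(),
                             mode = c("roi", "voxel"),
                             grid = dmn_grid(6), atlas = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "cohort_spec"),
            subject_index >= 1,
            subject_index <= spec$n_group_a + spec$n_group_b)
  group <- if (subject_index <= spec$n_group_a) "a" else "b"
  corr <- if (group == "a") spec$corr_a else spec$corr_b
  amps <- if (group == "a") spec$deact_amp_a else spec$deact_amp_b
  if (mode == "voxel" && is.null(atlas))
    atlas <- build_atlas(grid, spec$node_set)
  runs <- vector("list", length(designs))
  names(runs) <- names(designs)
  for (r in seq_along(designs)) {
    set.seed((spec$rng_seed + subject_index * 1009L + r * 101L) %%
               .Machine$integer.max)
    sim <- simulate_run_signals(spec, designs[[r]], corr, amps)
    if (mode == "roi") {
      runs[[r]] <- bold_run(sim$node, designs[[r]], motion = sim$motion,
                            roi_names = spec$node_set$name)
    } else {
      runs[[r]] <- paint_voxel_run(sim, spec, designs[[r]], grid, atlas)
    }
  }
  structure(list(subject_id = sprintf("%s%02d", group, subject_index),
                 group = group, runs = runs,
                 truth = list(corr = corr, deact_amp = amps,
                              effect_size = spec$effect_size)),
            class = "synthetic_subject")
}

# paint node signals into their spheres; background brain voxels get the
# shared components plus independent noise
paint_voxel_run <- function(sim, spec, design, grid, atlas) {
  n <- design$acquisition$n_volumes
  brain <- brain_mask(grid)
  inb <- which(brain)
  nv <- prod(grid$dims)
  V <- matrix(0, length(inb), n)
  V[] <- stats::rnorm(length(inb) * n, sd = spec$noise_sd)
  V <- V + matrix(sim$shared, length(inb), n, byrow = TRUE)
  lab_in <- atlas$labels[inb]
  k <- nrow(spec$node_set)
  for (i in seq_len(k)) {
    rows <- which(lab_in == i)
    if (length(rows) == 0) stop("node ", spec$node_set$name[i],
                                " has no voxels on this grid")
    # node voxels: node signal (already holds shared part) + own noise
    V[rows, ] <- matrix(sim$node[i, ], length(rows), n, byrow = TRUE) +
      matrix(stats::rnorm(length(rows) * n, sd = spec$noise_sd),
             length(rows), n)
  }
  dm <- matrix(0, nv, n)
  dm[inb, ] <- V
  data <- array(dm, c(grid$dims, n))
  bold_run(data, design, affine = grid$affine, brain_mask = brain,
           motion = sim$motion)
}

#' Generate the full synthetic cohort
#'
#' @inheritParams generate_subject
#' @return list of `synthetic_subject`s (group a first, then group b) with
#'   attribute `spec`.
#' @export
generate_cohort <- function(spec, designs = canonical_designs(),
                            mode = c("roi", "voxel"),
                            grid = dmn_grid(6), atlas = NULL) {
  mode <- match.arg(mode)
  if (mode == "voxel" && is.null(atlas)) atlas <- build_atlas(grid, spec$node_set)
  n <- spec$n_group_a + spec$n_group_b
  out <- lapply(seq_len(n), function(i)
    generate_subject(spec, i, designs, mode, grid, atlas))
  attr(out, "spec") <- spec
  out
}

#' Write a cohort's text artefacts (designs, motion, manifest)
#'
#' Writes per-run design TSVs (+ acquisition sidecars), per-run motion
#' tables and a JSON manifest holding the ground-truth spec.  Voxel data is
#' an in-memory representation in this package and is not serialised here.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- attr(cohort, "spec")
  for (s in cohort) {
    sd <- file.path(dir, s$subject_id)
    dir.create(sd, showWarnings = FALSE)
    for (rn in names(s$runs)) {
      write_design(s$runs[[rn]]$design, file.path(sd, paste0(rn, "_design.tsv")))
      utils::write.table(s$runs[[rn]]$motion,
                         file.path(sd, paste0(rn, "_motion.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
  }
  manifest <- list(
    n_group_a = spec$n_group_a, n_group_b = spec$n_group_b,
    effect_size = spec$effect_size, rng_seed = spec$rng_seed,
    nodes = spec$node_set,
    corr_a = spec$corr_a, corr_b = spec$corr_b,
    deact_amp_a = spec$deact_amp_a, deact_amp_b = spec$deact_amp_b,
    noise_sd = spec$noise_sd, drift_slope = spec$drift_slope,
    global_amp = spec$global_amp, motion_coupling = spec$motion_coupling,
    subjects = vapply(cohort, `[[`, "", "subject_id"),
    groups = vapply(cohort, `[[`, "", "group"))
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
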