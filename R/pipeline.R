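#' Default pipeline configuration
#'
#' All tunables of the analysis chain in one validated list.  Unknown keys
#' in `overrides` are rejected.
#'
#' @param overrides named list of settings to change.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    seed = 42L,              # master RNG seed
    mode = "roi",            # "roi" (fast) or "voxel"
    voxel_mm = 6,            # grid resolution in voxel mode
    effect_size = 0.3,       # planted MPFC coupling deficit
    n_group_a = 13L,
    n_group_b = 14L,
    lag = 6,                 # rest-block head trim, seconds
    append_threshold = 20,   # rest duration below which task lag is appended
    seed_radius = 6,         # connectivity seed radius, mm
    node_radius = 8,         # synthetic node sphere radius, mm (coarse
                             # grids need >= the voxel half-diagonal)
    voxel_p = 0.001,         # voxelwise threshold for cluster inference
    alpha = 0.05,            # family-wise error target
    n_sim = 10000L,          # Monte-Carlo simulations for extent threshold
    k_min_override = NULL,   # fixed extent threshold, skips simulation
    connectivity = 18L,      # cluster neighbour rule
    l2 = 1,                  # classifier L2 penalty
    fraction = 0.005,        # informative-connection fraction
    p_chance = 0.5)          # binomial chance level
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file of overrides.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Per-subject pseudo-resting-state preprocessing
#'
#' Excises rest blocks from every run, concatenates them, builds the
#' nuisance set (motion + mean motion + per-session trends + tissue/global
#' means) and regresses it out.
#'
#' @param subject a `synthetic_subject` (or any list with `runs` of
#'   [bold_run()]s).
#' @param lag,append_threshold see [excise_rest_blocks()].
#' @param masks tissue masks for voxel mode (default: template stand-ins
#'   computed from the run grid).
#' @return the cleaned, concatenated `rest_series`.
#' @export
preprocess_subject <- function(subject, lag = 6, append_threshold = 20,
                               masks = NULL) {
  series <- concatenate_runs(lapply(subject$runs, excise_rest_blocks,
                                    lag = lag,
                                    append_threshold = append_threshold))
  if (series$mode == "voxel" && is.null(masks)) {
    d <- dim(series$data)[1:3]
    grid <- list(dims = d, voxel_mm = diag(series$affine)[1:3],
                 affine = series$affine)
    masks <- tissue_masks(grid)
  }
  nuis <- build_nuisance(series, masks = if (series$mode == "voxel") masks)
  regress_out(series, nuis)
}

#' Subject-level connectivity features
#'
#' For a cleaned series: the ROI-by-ROI Fisher z matrix, its upper-triangle
#' feature vector, and (voxel mode) the three averaged seed z maps.
#'
#' @param series a cleaned `rest_series`.
#' @param atlas atlas for voxel mode (NULL in roi mode).
#' @param seeds seed list (default [default_seeds()]), used in voxel mode.
#' @return list: `matrix` (`connectivity_matrix`), `features` (named z
#'   vector), `dmn_map` (voxel mode only), `seed_features` (voxel mode:
#'   named list of seed-to-ROI z vectors).
#' @export
subject_connectivity <- function(series, atlas = NULL,
                                 seeds = default_seeds()) {
  # seed-sphere voxels are removed from ROIs only for seed-based features;
  # the full matrix uses the intact ROIs
  cm <- roi_matrix(series, atlas)
  out <- list(matrix = cm, features = matrix_features(cm))
  if (series$mode == "voxel") {
    maps <- lapply(seeds, function(s) seed_map(series, s))
    out$dmn_map <- average_dmn_map(maps)
    out$seed_maps <- maps
    out$seed_features <- lapply(seeds, function(s)
      seed_to_roi_vector(series, s, atlas))
  }
  out
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Synthesize -> excise rest -> clean -> connectivity -> group inference ->
#' LOOCV classification.  In roi mode the deactivation GLM and group tests
#' run on node signals; voxel mode additionally produces seed z maps and a
#' cluster-thresholded group difference map.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for the JSON report and summary.
#' @return list of class `pipeline_result`: `classification`,
#'   `informative`, `group_mpfc` (two-sample test on MPFC-PCC z),
#'   `deactivation` (group test on rest-vs-task contrast per node),
#'   `config`, plus `cluster_table`/`k_min` in voxel mode.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- make_dmn_cohort_spec(effect_size = config$effect_size,
                               seed = config$seed,
                               n_group_a = config$n_group_a,
                               n_group_b = config$n_group_b,
                               nodes = default_nodes(config$node_radius))
  designs <- canonical_designs()
  voxel <- config$mode == "voxel"
  grid <- if (voxel) dmn_grid(config$voxel_mm)
  atlas <- if (voxel) build_atlas(grid, spec$node_set)
  seeds <- default_seeds(config$seed_radius)
  n <- spec$n_group_a + spec$n_group_b

  features <- NULL
  mpfc_pcc_z <- numeric(n)
  deact <- NULL
  groups <- character(n)
  dmn_zmaps <- if (voxel) matrix(NA_real_, n, prod(grid$dims))
  masks <- if (voxel) tissue_masks(grid)

  for (i in seq_len(n)) {
    subj <- generate_subject(spec, i, designs, config$mode,
                             grid = if (voxel) grid else dmn_grid(),
                             atlas = atlas)
    groups[i] <- subj$group
    cleaned <- preprocess_subject(subj, lag = config$lag,
                                  append_threshold = config$append_threshold,
                                  masks = masks)
    conn <- subject_connectivity(cleaned, atlas, seeds)
    if (is.null(features))
      features <- matrix(NA_real_, n, length(conn$features),
                         dimnames = list(NULL, names(conn$features)))
    features[i, ] <- conn$features
    zi <- conn$matrix$z_values
    rn <- conn$matrix$roi_names
    mpfc_pcc_z[i] <- zi[match("MPFC", rn), match("PCC", rn)]
    if (voxel) dmn_zmaps[i, ] <- as.vector(conn$dmn_map$z_map)

    # rest-vs-task deactivation contrast per node (roi mode GLM)
    if (!voxel) {
      eff <- vapply(subj$runs, function(run) {
        X <- build_design_matrix(run$design)
        cn <- setdiff(colnames(X$columns), "intercept")
        ct <- stats::setNames(rep(-1 / length(cn), length(cn)), cn)
        fit_glm(run, X, ct)$effect  # rest minus task, per node
      }, numeric(nrow(subj$runs[[1]]$data)))
      deact <- rbind(deact, rowMeans(eff))
    }
  }

  tb <- feature_table(features, groups, positive_class = "a")
  cls <- loocv_classify(tb, l2 = config$l2, p_chance = config$p_chance)
  info <- informative_connections(cls$fold_weights, config$fraction,
                                  mean_correlations = colMeans(tanh(features)))
  grp <- group_ttest(matrix(mpfc_pcc_z, ncol = 1), groups)
  res <- list(classification = cls, informative = info,
              group_mpfc = list(t = grp$values, df = grp$df, p = grp$p),
              groups = groups, mpfc_pcc_z = mpfc_pcc_z,
              feature_table = tb, config = config)
  if (!voxel) {
    gd <- group_ttest(deact, groups)
    res$deactivation <- data.frame(node = spec$node_set$name,
                                   t = gd$values, p = gd$p)
  } else {
    gt <- group_ttest(dmn_zmaps, groups)
    k_min <- config$k_min_override %||%
      cluster_extent_threshold(brain_mask(grid), smoothness_fwhm = 0,
                               voxel_p = config$voxel_p,
                               n_sim = config$n_sim, alpha = config$alpha,
                               connectivity = config$connectivity,
                               voxel_mm = config$voxel_mm,
                               seed = config$seed + 1L)
    tcrit <- stats::qt(1 - config$voxel_p / 2, gt$df)
    tmap <- array(gt$values, grid$dims)
    tmap[!brain_mask(grid)] <- 0
    res$k_min <- as.integer(k_min)
    res$cluster_table <- extract_clusters(tmap, tcrit, k_min,
                                          config$connectivity,
                                          affine = grid$affine,
                                          direction = "two.sided")
    res$group_tmap <- tmap
  }
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_report(res, out_dir)
  res
}

#' Write a pipeline report (JSON + human-readable summary)
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cls <- result$classification
  report <- list(
    config = unclass(result$config),
    classification = list(
      n = cls$n, n_correct = cls$n_correct,
      accuracy_percent = cls$accuracy_percent,
      sensitivity = unname(cls$sensitivity),
      specificity = unname(cls$specificity),
      p_value = cls$p_value, p_chance = cls$p_chance),
    group_mpfc = result$group_mpfc,
    informative_positive = result$informative$positive,
    informative_negative = result$informative$negative,
    k_min = result$k_min)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(cls$per_fold, file.path(out_dir, "per_fold.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- c(
    sprintf("dmnclass pipeline (mode=%s, seed=%d, effect=%.2f)",
            result$config$mode, result$config$seed,
            result$config$effect_size),
    sprintf("LOOCV accuracy: %d/%d = %.2f%% (sens %.1f%%, spec %.1f%%, binomial p = %.4g)",
            cls$n_correct, cls$n, cls$accuracy_percent,
            100 * cls$sensitivity, 100 * cls$specificity, cls$p_value),
    sprintf("Group MPFC-PCC z difference: t(%d) = %.2f, p = %.4g",
            result$group_mpfc$df, result$group_mpfc$t, result$group_mpfc$p))
  writeLines(summ, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$classification)
  cat(sprintf("group MPFC-PCC z: t(%d) = %.2f, p = %.4g\n",
              x$group_mpfc$df, x$group_mpfc$t, x$group_mpfc$p))
  invisible(x)
}
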