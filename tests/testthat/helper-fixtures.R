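# shared fixtures, built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# simple alternating rest/task design: n_rest rest blocks of rest_dur
# seconds, task blocks of task_dur seconds in between (rest first)
alt_design <- function(n_rest = 5, rest_dur = 24, task_dur = 30, tr = 1,
                       study_id = "toy") {
  durs <- numeric(0)
  conds <- character(0)
  for (i in seq_len(n_rest)) {
    durs <- c(durs, rest_dur)
    conds <- c(conds, "rest")
    if (i < n_rest) {
      durs <- c(durs, task_dur)
      conds <- c(conds, "task")
    }
  }
  blocks <- data.frame(onset = cumsum(c(0, durs[-length(durs)])),
                       duration = durs, condition = conds)
  session_design(study_id, blocks,
                 acquisition_params(tr = tr, n_volumes = ceiling(sum(durs) / tr)))
}

# a design consisting of one long rest block
rest_only_design <- function(seconds = 300, tr = 1) {
  session_design("restonly",
                 data.frame(onset = 0, duration = seconds, condition = "rest"),
                 acquisition_params(tr = tr, n_volumes = ceiling(seconds / tr)))
}

# roi-mode rest_series with given data matrix (rois x t), one segment
toy_series <- function(data, tr = 1, run = "toy") {
  structure(list(data = data, tr = tr,
                 segments = data.frame(run = run, block = 1L,
                                       source_start = 0L,
                                       source_end = ncol(data),
                                       n = ncol(data)),
                 retained = seq_len(ncol(data)) - 1L,
                 affine = NULL, brain_mask = NULL, motion = NULL,
                 mode = "roi"),
            class = "rest_series")
}

# voxel-mode rest_series of pure noise on a grid, one segment
noise_voxel_series <- function(grid, nt, sd = 1, seed = 1) {
  set.seed(seed)
  data <- array(stats::rnorm(prod(grid$dims) * nt, sd = sd),
                c(grid$dims, nt))
  structure(list(data = data, tr = 1,
                 segments = data.frame(run = "noise", block = 1L,
                                       source_start = 0L, source_end = nt,
                                       n = nt),
                 retained = seq_len(nt) - 1L,
                 affine = grid$affine, brain_mask = brain_mask(grid),
                 motion = NULL, mode = "voxel"),
            class = "rest_series")
}

# coarse-grid settings used by voxel-mode tests: 12 mm voxels need node
# spheres of at least the voxel half-diagonal (10.4 mm)
coarse_grid <- function() dmn_grid(12)
coarse_nodes <- function() default_nodes(11)
coarse_seeds <- function() default_seeds(9)

# per-fold table with the given per-group correct counts
per_fold_from_counts <- function(correct_a = 10, n_a = 13,
                                 correct_b = 11, n_b = 14) {
  truth <- c(rep("asd", n_a), rep("control", n_b))
  pred <- c(rep("asd", correct_a), rep("control", n_a - correct_a),
            rep("control", correct_b), rep("asd", n_b - correct_b))
  data.frame(subject = paste0("S", seq_along(truth)), truth = truth,
             predicted = pred, stringsAsFactors = FALSE)
}
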