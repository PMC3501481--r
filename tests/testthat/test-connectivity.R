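test_that("default seeds carry the canonical coordinates", {
  seeds <- default_seeds()
  expect_length(seeds, 3)
  expect_equal(seeds$MPFC$center_mni, c(-1, 47, -4))
  expect_equal(seeds$PCC$center_mni, c(-5, -49, 40))
  expect_equal(seeds$AG$center_mni, c(-45, -67, 36))
  expect_true(all(vapply(seeds, function(s) s$radius, 1) > 0))
})

test_that("fisher z is the clamped atanh", {
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(0), 0)
  # identity on the safe range, monotone
  r <- seq(-0.999, 0.999, length.out = 201)
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0))
  # clamped at +-1, still finite
  expect_true(is.finite(fisher_z(1)))
  expect_gt(fisher_z(1), 8)
  expect_equal(fisher_z(-1), -fisher_z(1))
})

test_that("seed timecourses average the sphere voxels", {
  g <- coarse_grid()
  nt <- 40
  ser <- noise_voxel_series(g, nt, seed = 5)
  seeds <- coarse_seeds()

  # uniform volume -> constant series
  seru <- ser
  seru$data[] <- 3.25
  expect_equal(seed_timecourse(seru, seeds$MPFC), rep(3.25, nt))

  # noise-free planted common signal in the sphere is recovered exactly
  set.seed(6)
  s <- rnorm(nt, sd = 3)
  vox <- which(sphere_mask(g, seeds$PCC$center_mni, seeds$PCC$radius) &
                 ser$brain_mask)
  expect_gt(length(vox), 0)
  d <- dim(ser$data)
  m <- matrix(ser$data, prod(d[1:3]), nt)
  m[vox, ] <- matrix(s, length(vox), nt, byrow = TRUE)
  serp <- ser
  serp$data <- array(m, d)
  expect_gt(cor(seed_timecourse(serp, seeds$PCC), s), 0.99)

  # a seed outside the brain errors
  far <- list(name = "far", center_mni = c(0, 85, 100), radius = 4)
  expect_error(seed_timecourse(ser, far), "does not intersect")
})

test_that("seed maps are correlations with the documented edge policies", {
  g <- coarse_grid()
  ser <- noise_voxel_series(g, 60, seed = 8)
  seeds <- coarse_seeds()

  # a voxel holding exactly the seed timecourse correlates at clamped z
  tc <- seed_timecourse(ser, seeds$MPFC)
  d <- dim(ser$data)
  m <- matrix(ser$data, prod(d[1:3]), 60)
  m[1, ] <- tc
  m[2, ] <- 0                      # zero-variance voxel
  ser$data <- array(m, d)
  cmap <- seed_map(ser, seeds$MPFC)
  expect_gt(cmap$z_map[1], 8)
  expect_equal(cmap$r_map[2], 0)
  expect_true(2 %in% cmap$flagged)
  expect_equal(cmap$z_map[100], atanh(cmap$r_map[100]), tolerance = 1e-12)
  expect_equal(cmap$n_timepoints, 60)

  # independent noise voxels stay weakly correlated at n = 285
  ser285 <- noise_voxel_series(dmn_grid(36), 285, seed = 9)
  sd36 <- list(name = "c", center_mni = c(0, -18, 18), radius = 30)
  cm285 <- seed_map(ser285, sd36)
  inb <- which(ser285$brain_mask &
                 !sphere_mask(dmn_grid(36), sd36$center_mni, sd36$radius))
  expect_lt(max(abs(cm285$r_map[inb])), 0.3)
  expect_lt(mean(abs(cm285$r_map[inb]) > 0.2), 0.01)

  expect_error(seed_map(noise_voxel_series(g, 5), seeds$MPFC), ">= 10")
})

test_that("dmn averaging is the voxelwise mean of z maps", {
  g <- dmn_grid(36)
  ser <- noise_voxel_series(g, 30, seed = 10)
  sd1 <- list(name = "c", center_mni = c(0, -18, 18), radius = 30)
  m1 <- seed_map(ser, sd1)

  # three identical maps -> the same map
  avg <- average_dmn_map(list(m1, m1, m1))
  expect_equal(avg$z_map, m1$z_map, tolerance = 1e-12)

  # hand mean at a voxel
  m2 <- m1; m2$z_map[] <- 0.6
  m3 <- m1; m3$z_map[] <- 0.9
  m1b <- m1; m1b$z_map[] <- 0.3
  expect_equal(average_dmn_map(list(m1b, m2, m3))$z_map[1], 0.6)

  # grid mismatch errors
  mother <- seed_map(noise_voxel_series(coarse_grid(), 30, seed = 11),
                     coarse_seeds()$MPFC)
  expect_error(average_dmn_map(list(m1, mother)), "grid mismatch")
})

test_that("roi matrices are symmetric z matrices with fixed ordering", {
  set.seed(12)
  k <- 8; nt <- 120
  tc <- matrix(rnorm(k * nt), k, nt)
  tc[3, ] <- tc[5, ]  # two ROIs carrying identical signal
  rownames(tc) <- paste0("R", 1:k)
  cm <- roi_matrix(toy_series(tc))
  expect_true(is.na(cm$z_values[1, 1]))
  off <- cm$z_values[upper.tri(cm$z_values)]
  expect_true(all(is.finite(off)))
  expect_equal(cm$z_values, t(cm$z_values), tolerance = 1e-12)
  expect_gt(cm$z_values[3, 5], 8)  # planted identical pair

  # null 99.9th percentile at this nt is far below the planted pair
  null_z <- quantile(abs(off[abs(off) < 8]), 0.999)
  expect_gt(cm$z_values[3, 5], null_z)

  feats <- matrix_features(cm)
  expect_length(feats, k * (k - 1) / 2)
  expect_equal(unname(feats["R3--R5"]), cm$z_values[3, 5])
})

test_that("atlas bookkeeping: 116 labels minus 14 exclusions is 102 ROIs", {
  g <- coarse_grid()
  atlas <- build_atlas(g, coarse_nodes())
  ids <- sort(unique(as.vector(atlas$labels)))
  ids <- ids[ids > 0]
  expect_length(ids, 116)
  expect_length(atlas$exclude, 14)

  ser <- noise_voxel_series(g, 40, seed = 13)
  cm <- roi_matrix(ser, atlas)
  expect_equal(dim(cm$z_values), c(102, 102))
  expect_length(matrix_features(cm), 102 * 101 / 2)

  # seed-based features: one z per retained ROI
  v <- seed_to_roi_vector(ser, coarse_seeds()$MPFC, atlas)
  expect_true(length(v) %in% c(101, 102))  # seed may empty its own ROI
  expect_true(all(is.finite(v)))
})

test_that("zero-noise cohort recovers planted correlations through the pipeline", {
  spec <- make_dmn_cohort_spec(0.3, seed = 14, nodes = coarse_nodes(),
                               noise_sd = 0, drift_slope = 0,
                               global_amp = 0, motion_coupling = 0)
  g <- coarse_grid()
  atlas <- build_atlas(g, spec$node_set)
  subj <- generate_subject(spec, 14, canonical_designs(), "voxel",
                           grid = g, atlas = atlas)  # group b
  ser <- concatenate_runs(lapply(subj$runs, excise_rest_blocks))
  cm <- suppressWarnings(roi_matrix(ser, atlas))
  rn <- cm$roi_names
  for (pair in list(c("MPFC", "PCC"), c("PCC", "AG_L"), c("MPFC", "V1_R"))) {
    z <- cm$z_values[match(pair[1], rn), match(pair[2], rn)]
    target <- atanh(spec$corr_b[pair[1], pair[2]])
    expect_equal(z, target, tolerance = 0.15)
  }
})
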