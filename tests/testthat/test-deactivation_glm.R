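test_that("design matrix columns behave like HRF-convolved boxcars", {
  des <- alt_design(n_rest = 3, rest_dur = 24, task_dur = 24)
  X <- build_design_matrix(des)
  expect_true("task" %in% colnames(X$columns))
  expect_true("intercept" %in% colnames(X$columns))

  # a condition with no blocks gives an all-zero regressor
  expect_true(all(condition_regressor(des, "absent") == 0))

  # single 24-s boxcar: peak 5-8 s after onset, not before
  one <- session_design("one",
                        data.frame(onset = c(0, 30), duration = c(24, 24),
                                   condition = c("rest", "task")),
                        acquisition_params(tr = 1, n_volumes = 120))
  reg <- condition_regressor(one, "task")
  pk <- which.max(reg) - 1  # 0-based volume of the peak
  expect_gte(pk - 30, 5)
  expect_lte(pk - 30, 8 + 24)  # hemodynamic lag, at most to block end
  expect_true(all(reg[1:30] < 1e-12))  # causal kernel: silent before onset

  # column integral = block seconds x unit-area kernel once the response
  # has fully decayed inside the run
  expect_equal(sum(reg), 24, tolerance = 1e-6)

  # unknown condition label in collapse map errors
  expect_error(build_design_matrix(des, collapse = list(lang = "nope")),
               "unknown condition")
})

test_that("fit_glm recovers planted amplitudes and calibrates under null", {
  des <- alt_design(n_rest = 6, rest_dur = 24, task_dur = 24)
  n <- des$acquisition$n_volumes
  X <- build_design_matrix(des)
  task <- X$columns[, "task"]

  # planted +1 amplitude, contrast rest - task  ->  strongly negative t
  set.seed(21)
  nvox <- 50
  Y <- matrix(rnorm(n * nvox), n, nvox)
  Y[, 1:10] <- Y[, 1:10] + outer(task, rep(1, 10))
  sm <- fit_glm(Y, X, c(task = -1))
  expect_true(all(sm$values[1:10] < -3))
  expect_equal(sm$df, n - 2)

  # zero contrast -> t identically zero
  sm0 <- fit_glm(Y, X, c(task = 0))
  expect_true(all(sm0$values == 0))

  # null calibration: two-sided p<0.001 exceedance near 0.002
  set.seed(22)
  Yn <- matrix(rnorm(n * 10000), n)
  smn <- fit_glm(Yn, X, c(task = 1))
  crit <- qt(1 - 0.001, smn$df)
  rate <- mean(abs(smn$values) > crit)
  expect_gt(rate, 0.001)
  expect_lt(rate, 0.003)

  # collinear columns are dropped with a warning; contrasts on them error
  Xc <- cbind(X$columns, dup = X$columns[, "task"])
  expect_warning(fit_glm(Y, Xc, c(task = 1)), "collinear")
  expect_error(suppressWarnings(fit_glm(Y, Xc, c(dup = 1))), "dropped")
})

test_that("group t-test matches the closed form and the t.test oracle", {
  # identical groups -> t = 0
  m <- matrix(rep(1:5, each = 6), 6, 5)
  gt0 <- group_ttest(m, rep(c("a", "b"), 3))
  expect_true(all(abs(gt0$values) < 1e-12))

  # closed-form pooled t for two groups of constants + jitter
  set.seed(31)
  n1 <- 13; n2 <- 14
  a <- matrix(2 + rnorm(n1 * 4, sd = 0.7), n1, 4)
  b <- matrix(1 + rnorm(n2 * 4, sd = 0.7), n2, 4)
  gt <- group_ttest(rbind(a, b), c(rep("a", n1), rep("b", n2)))
  for (j in 1:4) {
    or <- t.test(a[, j], b[, j], var.equal = TRUE)
    expect_equal(unname(gt$values[j]), unname(or$statistic), tolerance = 1e-10)
    expect_equal(gt$p[j], or$p.value, tolerance = 1e-10)
  }
  expect_equal(gt$df, n1 + n2 - 2)

  # planted group shift is recovered where planted
  shift <- matrix(0, n1 + n2, 50)
  shift[1:n1, 1:5] <- 1.5
  noise <- matrix(rnorm((n1 + n2) * 50, sd = 0.5), n1 + n2, 50)
  gts <- group_ttest(shift + noise, c(rep("a", n1), rep("b", n2)))
  expect_true(all(gts$values[1:5] > 3))

  expect_error(group_ttest(rbind(a, b[1, , drop = FALSE]),
                           c(rep("a", n1), "b")), ">= 2")
})

test_that("BH step-up matches hand computation and brute force", {
  # hand-worked: thresholds q*i/m = {1/60, 1/30, 1/20}
  rej <- fdr_threshold(c(0.001, 0.02, 0.9), q = 0.05)
  expect_equal(as.logical(rej), c(TRUE, TRUE, FALSE))

  expect_equal(as.logical(fdr_threshold(rep(1, 5), 0.05)), rep(FALSE, 5))
  expect_length(fdr_threshold(numeric(0)), 0)

  # brute-force oracle: largest i with p_(i) <= q i / m, reject all below
  bh_brute <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ok <- which(p[o] <= q * seq_len(m) / m)
    rej <- rep(FALSE, m)
    if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
    rej
  }
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_equal(as.logical(fdr_threshold(p, q)), bh_brute(p, q))
  }
})

test_that("cluster extraction finds hand-checkable components", {
  # single suprathreshold voxel with k_min 2 -> empty table
  v <- array(0, c(6, 6, 6))
  v[3, 3, 3] <- 5
  expect_equal(nrow(extract_clusters(v, 3, k_min = 2)), 0)

  # two touching voxels under 26-connectivity -> one cluster of 2
  v[4, 4, 4] <- 5
  t26 <- extract_clusters(v, 3, k_min = 2, connectivity = 26)
  expect_equal(t26$k, 2)
  # ... but separate under 6-connectivity
  t6 <- extract_clusters(v, 3, k_min = 1, connectivity = 6)
  expect_equal(sort(t6$k), c(1, 1))

  # planted 5x5x5 blob survives k_min = 110 (125 >= 110)
  blob <- array(0, c(12, 12, 12))
  blob[4:8, 4:8, 4:8] <- 4
  tb <- extract_clusters(blob, 3, k_min = 110)
  expect_equal(tb$k, 125)

  # peak coordinates go through the affine
  g <- dmn_grid(12)
  vv <- array(0, g$dims)
  vv[1, 1, 1] <- 10
  tc <- extract_clusters(vv, 3, k_min = 1, affine = g$affine)
  expect_equal(c(tc$peak_x, tc$peak_y, tc$peak_z),
               drop(vox_to_mm(g$affine, c(0, 0, 0))))

  # negative clusters via direction = "less"
  neg <- array(0, c(5, 5, 5)); neg[2, 2, 2] <- -4
  expect_equal(nrow(extract_clusters(neg, 3, direction = "greater")), 0)
  expect_equal(extract_clusters(neg, 3, direction = "less")$peak_stat, -4)
})

test_that("cluster extraction is invariant to voxel relabelling order", {
  set.seed(51)
  v <- array(rnorm(10^3), c(10, 10, 10))
  t1 <- extract_clusters(v, 1.5, k_min = 2)
  # flip all axes: same clusters, mirrored peaks
  vf <- v[10:1, 10:1, 10:1]
  t2 <- extract_clusters(vf, 1.5, k_min = 2)
  expect_equal(sort(t1$k), sort(t2$k))
  expect_equal(sort(t1$peak_stat), sort(t2$peak_stat))
})

test_that("monte-carlo extent threshold honours its bounds and monotonicity", {
  mask <- array(TRUE, c(10, 10, 10))
  expect_equal(cluster_extent_threshold(mask, alpha = 1), 1L)
  expect_warning(cluster_extent_threshold(mask, n_sim = 50, seed = 1),
                 "unstable")

  # independent-voxel regime: k_min stays tiny
  k0 <- cluster_extent_threshold(mask, smoothness_fwhm = 0, voxel_p = 0.001,
                                 n_sim = 2000, seed = 7, voxel_mm = 3)
  expect_true(k0 %in% c(1L, 2L))

  # k_min is non-decreasing in smoothness
  ks <- vapply(c(0, 6, 12), function(fw)
    as.integer(cluster_extent_threshold(mask, smoothness_fwhm = fw,
                                        voxel_p = 0.001, n_sim = 2000,
                                        seed = 7, voxel_mm = 3)),
    1L)
  expect_true(all(diff(ks) >= 0))
})
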