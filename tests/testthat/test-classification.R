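sep_table <- function(n1 = 13, n2 = 14, d = 10, sep = 3, sd = 1, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n1 * d, mean = 0, sd = sd), n1, d),
             matrix(rnorm(n2 * d, mean = sep * sd, sd = sd), n2, d))
  feature_table(X, c(rep("asd", n1), rep("control", n2)),
                positive_class = "asd")
}

test_that("LOOCV separates well-separated clusters perfectly", {
  tb <- sep_table(sep = 3)
  res <- loocv_classify(tb)
  expect_equal(res$accuracy_percent, 100)
  expect_equal(res$n_correct, 27)
  expect_equal(unname(res$sensitivity), 1)
  expect_equal(unname(res$specificity), 1)
  expect_equal(res$p_value, 0.5^27, tolerance = 1e-12)
  expect_equal(nrow(res$per_fold), 27)
  expect_equal(dim(res$fold_weights), c(27L, 10L))
})

test_that("LOOCV is deterministic and invariant to subject ordering", {
  tb <- sep_table(sep = 1, seed = 4)
  r1 <- loocv_classify(tb)
  r2 <- loocv_classify(tb)
  expect_identical(r1$per_fold, r2$per_fold)

  perm <- sample(seq_len(nrow(tb$features)))
  tbp <- feature_table(tb$features[perm, ], tb$labels[perm],
                       subjects = tb$subjects[perm],
                       positive_class = "asd")
  rp <- loocv_classify(tbp)
  expect_equal(rp$accuracy_percent, r1$accuracy_percent)
  o <- match(tb$subjects, tbp$subjects)
  expect_equal(rp$per_fold$predicted[o], r1$per_fold$predicted)
})

test_that("metrics recompute from the per-fold table", {
  tb <- sep_table(sep = 1.2, seed = 5)
  res <- loocv_classify(tb)
  pf <- res$per_fold
  expect_equal(res$n_correct, sum(pf$predicted == pf$truth))
  expect_equal(res$accuracy_percent, 100 * res$n_correct / res$n)
  met <- compute_metrics(pf, "asd")
  expect_equal(unname(res$sensitivity), unname(met["sensitivity"]))
  expect_equal(unname(res$specificity), unname(met["specificity"]))

  # single-class training folds are refused
  Xs <- matrix(rnorm(8), 4, 2)
  expect_error(feature_table(Xs, c("a", "a", "a", "b")), ">= 2")
})

test_that("permuted labels drive accuracy to chance", {
  set.seed(6)
  X <- matrix(rnorm(27 * 10), 27, 10)
  tb <- feature_table(X, c(rep("asd", 13), rep("control", 14)),
                      positive_class = "asd")
  null_acc <- permutation_null_accuracy(tb, n_perm = 200, seed = 7)
  # LOOCV under permutation sits at or slightly below nominal chance: the
  # held-out subject's class is always under-represented in its training
  # fold, which biases the null mean a few points under 50%
  expect_lt(mean(null_acc), 53)
  expect_gt(mean(null_acc), 35)
  # no residual information: the null's central mass spans chance
  expect_gt(quantile(null_acc, 0.95), 50)
})

test_that("binomial significance is the exact upper tail", {
  expect_equal(binomial_significance(27, 27, 0.5), 2^-27, tolerance = 1e-15)
  expect_equal(binomial_significance(0, 27, 0.5), 1)
  # exact summation oracle over binomial coefficients
  oracle <- sum(choose(27, 19:27)) / 2^27
  expect_equal(binomial_significance(19, 27, 0.5), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.0261, tolerance = 1e-2)  # = 0.02612 exactly
  # matches pbinom across a grid of cases
  for (n in c(5, 27, 60)) for (k in c(0, 1, n %/% 2, n)) for (p in c(0.3, 0.5))
    expect_equal(binomial_significance(k, n, p),
                 pbinom(k - 1, n, p, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("informative connections rank planted discriminative features", {
  # ceiling arithmetic at the published feature count
  W <- matrix(rnorm(27 * 5151), 27, 5151,
              dimnames = list(NULL, paste0("c", 1:5151)))
  ic <- informative_connections(W, 0.005)
  expect_equal(ic$n_top, 26L)
  expect_equal(nrow(ic$positive), 26)
  expect_equal(nrow(ic$negative), 26)
  expect_error(informative_connections(W, 0), "fraction")

  # all-equal weights: deterministic tie-break in feature order, flagged
  We <- matrix(1, 3, 6, dimnames = list(NULL, paste0("f", 1:6)))
  ice <- informative_connections(We, 0.4)
  expect_true(ice$ties)
  expect_equal(ice$positive$connection, c("f1", "f2", "f3"))

  # a planted single discriminative feature tops the list
  hits <- 0
  for (rep in 1:20) {
    set.seed(100 + rep)
    n1 <- 13; n2 <- 14; d <- 40
    X <- matrix(rnorm((n1 + n2) * d), n1 + n2, d,
                dimnames = list(NULL, paste0("f", 1:d)))
    X[1:n1, 17] <- X[1:n1, 17] + 3
    tb <- feature_table(X, c(rep("a", n1), rep("b", n2)),
                        positive_class = "a")
    res <- loocv_classify(tb)
    ic <- informative_connections(res$fold_weights, fraction = 1 / d)
    hits <- hits + (ic$positive$connection[1] == "f17")
  }
  expect_gte(hits, 19)
})

test_that("groupwise feature tests control the family-wise error", {
  # matched group distributions -> nothing significant (deterministic)
  base <- rep(c(-1, 1), length.out = 27)
  X0 <- outer(base, seq(0.5, 2, length.out = 102))
  tb0 <- feature_table(X0, c(rep("a", 13), rep("b", 14)),
                       positive_class = "a")
  gt0 <- groupwise_feature_tests(tb0)
  expect_equal(sum(gt0$significant), 0)

  # a 2-sd mean shift in 1 of 102 features: empirical detection rate must
  # match the exact noncentral-t power of the Bonferroni test (0.88 at
  # n = 13 + 14), within Monte-Carlo error
  n_rep <- 40
  found <- 0
  for (rep in seq_len(n_rep)) {
    set.seed(200 + rep)
    X <- matrix(rnorm(27 * 102), 27, 102,
                dimnames = list(NULL, paste0("f", 1:102)))
    X[1:13, 55] <- X[1:13, 55] + 2
    tb <- feature_table(X, c(rep("a", 13), rep("b", 14)),
                        positive_class = "a")
    gt <- groupwise_feature_tests(tb, alpha = 0.05)
    found <- found + ("f55" %in% gt$feature[gt$significant])
  }
  ncp <- 2 / sqrt(1 / 13 + 1 / 14)
  crit <- qt(1 - 0.05 / 102 / 2, df = 25)
  power <- pt(crit, 25, ncp, lower.tail = FALSE) + pt(-crit, 25, ncp)
  se <- sqrt(power * (1 - power) / n_rep)
  expect_lt(abs(found / n_rep - power), 3 * se + 0.02)
  expect_gt(found / n_rep, 0.7)

  # bonferroni set is a subset of the uncorrected set
  set.seed(300)
  X <- matrix(rnorm(27 * 50), 27, 50)
  tb <- feature_table(X, c(rep("a", 13), rep("b", 14)), positive_class = "a")
  gt <- groupwise_feature_tests(tb, alpha = 0.05)
  expect_true(all(gt$p[gt$significant] <= 0.05))
})
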