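#' Assemble a subjects-by-features table for classification
#'
#' @param features subjects x features numeric matrix (no missing values).
#' @param labels group label per subject (2 classes, >= 2 subjects each).
#' @param subjects optional subject ids (default row names or S1..Sn).
#' @param positive_class label treated as the positive (clinical) class;
#'   default is the first level.
#' @return list of class `feature_table`.
#' @export
feature_table <- function(features, labels, subjects = NULL,
                          positive_class = NULL) {
  features <- as.matrix(features)
  if (anyNA(features)) stop("feature table contains missing values")
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  cls <- unique(labels)
  if (length(cls) != 2) stop("need exactly two classes")
  if (min(table(labels)) < 2) stop("need >= 2 subjects per class")
  if (is.null(positive_class)) positive_class <- cls[1]
  stopifnot(positive_class %in% cls)
  if (is.null(subjects))
    subjects <- rownames(features) %||% paste0("S", seq_len(nrow(features)))
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  structure(list(features = features, labels = labels, subjects = subjects,
                 feature_names = colnames(features),
                 positive_class = positive_class),
            class = "feature_table")
}

# L2-regularised logistic fit returning coefficients at one penalty.
# glmnet parameterisation: objective -loglik/n + lambda/2 * ||beta||^2.
ridge_logistic <- function(X, y01, lambda) {
  d <- ncol(X)
  pad <- d < 2
  if (pad) X <- cbind(X, 0)  # glmnet needs >= 2 columns; zero col is inert
  path <- lambda * c(64, 16, 4, 1)
  fit <- glmnet::glmnet(X, y01, family = "binomial", alpha = 0,
                        lambda = path, standardize = FALSE, intercept = TRUE)
  co <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  list(intercept = co[1], beta = co[2:(1 + d)])
}

#' Leave-one-out logistic-regression classification
#'
#' Each subject is held out once; an L2-regularised logistic regression is
#' trained on the rest (features standardised with training-fold statistics
#' only) and predicts the held-out subject at probability threshold 0.5.
#' A predicted probability of exactly 0.5 falls back to the training-fold
#' majority class.  Deterministic given the table and settings.
#'
#' @param table a [feature_table()].
#' @param l2 L2 penalty strength (glmnet lambda; default 1).  Plain
#'   unregularised logistic regression is ill-posed when features far
#'   outnumber subjects, so some regularisation is always applied.
#' @param p_chance chance probability for the binomial test (default 0.5;
#'   use `max(n1, n2) / n` for the class-prior convention).
#' @return list of class `classification_result`: `per_fold` data.frame
#'   (subject, truth, predicted, decision_value), `n_correct`,
#'   `accuracy_percent`, `sensitivity`, `specificity`, `p_value`, `n`,
#'   `p_chance`, `fold_weights` (folds x features, standardised space).
#' @export
loocv_classify <- function(table, l2 = 1, p_chance = 0.5) {
  stopifnot(inherits(table, "feature_table"))
  X <- table$features
  y <- table$labels
  n <- nrow(X)
  pos <- table$positive_class
  y01 <- as.integer(y == pos)
  preds <- character(n)
  dec <- numeric(n)
  W <- matrix(0, n, ncol(X), dimnames = list(NULL, table$feature_names))
  for (i in seq_len(n)) {
    ytr <- y01[-i]
    if (length(unique(ytr)) < 2)
      stop("training fold ", i, " contains a single class")
    Xtr <- X[-i, , drop = FALSE]
    mu <- colMeans(Xtr)
    sd <- apply(Xtr, 2, stats::sd)
    sd[sd == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sd, "/")
    xte <- (X[i, ] - mu) / sd
    fit <- ridge_logistic(Xtr, ytr, l2)
    eta <- fit$intercept + sum(fit$beta * xte)
    p <- 1 / (1 + exp(-eta))
    if (p == 0.5) {
      maj <- if (mean(ytr) >= 0.5) 1L else 0L
      preds[i] <- if (maj == 1L) pos else setdiff(unique(y), pos)
    } else {
      preds[i] <- if (p > 0.5) pos else setdiff(unique(y), pos)
    }
    dec[i] <- p
    W[i, ] <- fit$beta
  }
  per_fold <- data.frame(subject = table$subjects, truth = y,
                         predicted = preds, decision_value = dec,
                         stringsAsFactors = FALSE)
  n_correct <- sum(preds == y)
  met <- compute_metrics(per_fold, pos)
  structure(list(per_fold = per_fold, n_correct = n_correct, n = n,
                 accuracy_percent = 100 * n_correct / n,
                 sensitivity = met["sensitivity"],
                 specificity = met["specificity"],
                 p_value = binomial_significance(n_correct, n, p_chance),
                 p_chance = p_chance,
                 fold_weights = W,
                 positive_class = pos, l2 = l2),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "LOOCV logistic regression: %d/%d correct (%.2f%%), sens %.1f%%, spec %.1f%%, binomial p = %.4g\n",
    x$n_correct, x$n, x$accuracy_percent, 100 * x$sensitivity,
    100 * x$specificity, x$p_value))
  invisible(x)
}

#' Sensitivity and specificity from per-fold predictions
#'
#' Sensitivity is the proportion of the positive class correctly predicted
#' (TP / (TP + FN)); specificity the proportion of the other class
#' (TN / (TN + FP)).
#'
#' @param per_fold data.frame with columns `truth` and `predicted`.
#' @param positive_class the label counted as positive.
#' @return named numeric vector (proportions in \[0, 1\]).
#' @export
compute_metrics <- function(per_fold, positive_class) {
  truth <- per_fold$truth
  pred <- per_fold$predicted
  stopifnot(positive_class %in% truth, any(truth != positive_class))
  pos <- truth == positive_class
  c(sensitivity = mean(pred[pos] == truth[pos]),
    specificity = mean(pred[!pos] == truth[!pos]))
}

#' Exact binomial tail probability of a classification accuracy
#'
#' P(X >= n_correct) for X ~ B(n, p_chance), the probability of doing at
#' least this well when subjects are randomly labelled.  Terms are summed
#' from smallest to largest for numerical stability.
#'
#' @param n_correct number of correctly classified subjects.
#' @param n total subjects.
#' @param p_chance chance probability in (0, 1).
#' @return upper-tail p value.
#' @export
binomial_significance <- function(n_correct, n, p_chance = 0.5) {
  stopifnot(n_correct >= 0, n_correct <= n, p_chance > 0, p_chance < 1)
  if (n_correct == 0) return(1)
  k <- n_correct:n
  terms <- exp(lchoose(n, k) + k * log(p_chance) +
                 (n - k) * log1p(-p_chance))
  min(sum(sort(terms)), 1)
}

#' Most informative connections per class
#'
#' Averages classifier weights across folds and ranks connections by signed
#' weight: the most positive weights push the decision toward the positive
#' class, the most negative toward the other class.  Each list takes
#' `ceiling(fraction * d)` connections; exact weight ties are broken by
#' feature order and flagged.
#'
#' @param fold_weights folds x features weight matrix (named columns), e.g.
#'   `$fold_weights` of a [loocv_classify()] result.
#' @param fraction fraction of connections per class, in (0, 1\]
#'   (default 0.005, i.e. the top 0.5%).
#' @param mean_correlations optional named vector of mean feature values
#'   (e.g. mean z) reported alongside.
#' @return list of class `informative_connections`: `positive` and
#'   `negative` data.frames (connection, mean_weight, mean_correlation),
#'   `fraction`, `ties` flag.
#' @export
informative_connections <- function(fold_weights, fraction = 0.005,
                                    mean_correlations = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  w <- colMeans(fold_weights)
  d <- length(w)
  n_top <- as.integer(ceiling(fraction * d))
  mk <- function(ord) {
    sel <- ord[seq_len(n_top)]
    data.frame(connection = names(w)[sel], mean_weight = unname(w[sel]),
               mean_correlation = if (is.null(mean_correlations)) NA_real_
               else unname(mean_correlations[names(w)[sel]]),
               stringsAsFactors = FALSE)
  }
  ties <- anyDuplicated(w) > 0
  structure(list(positive = mk(order(-w)), negative = mk(order(w)),
                 fraction = fraction, n_top = n_top, ties = ties),
            class = "informative_connections")
}

#' Mass-univariate group differences on features
#'
#' Two-sample pooled-variance t test per feature with Bonferroni (default)
#' or Benjamini-Hochberg correction.
#'
#' @param table a [feature_table()].
#' @param alpha significance level (default 0.05).
#' @param correction "bonferroni" or "BH".
#' @return data.frame (feature, t, p, significant) ordered by p.
#' @export
groupwise_feature_tests <- function(table, alpha = 0.05,
                                    correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  stopifnot(inherits(table, "feature_table"))
  grp <- factor(table$labels,
                levels = c(table$positive_class,
                           setdiff(unique(table$labels),
                                   table$positive_class)))
  st <- group_ttest(table$features, grp)
  d <- ncol(table$features)
  sig <- if (correction == "bonferroni") st$p <= alpha / d
  else fdr_threshold(st$p, alpha)
  out <- data.frame(feature = table$feature_names, t = st$values, p = st$p,
                    significant = as.logical(sig), stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}

#' Permutation null distribution for LOOCV accuracy
#'
#' Re-runs [loocv_classify()] with group labels permuted; useful both as a
#' negative control and to situate an observed accuracy against chance.
#'
#' @param table a [feature_table()].
#' @param n_perm number of permutations.
#' @param l2,p_chance passed to [loocv_classify()].
#' @param seed RNG seed.
#' @return numeric vector of permuted accuracies (percent).
#' @export
permutation_null_accuracy <- function(table, n_perm = 100, l2 = 1,
                                      p_chance = 0.5, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  out <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample(table$labels)
    # a permutation can starve a training fold of one class; resample
    while (min(table(perm)) < 2) perm <- sample(table$labels)
    tb <- feature_table(table$features, perm,
                        subjects = table$subjects,
                        positive_class = table$positive_class)
    out[b] <- loocv_classify(tb, l2 = l2, p_chance = p_chance)$accuracy_percent
  }
  out
}
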