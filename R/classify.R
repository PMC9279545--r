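# Stratified fold assignment: within each class, observations are shuffled
# (seeded) and dealt round-robin, so fold class proportions match the data.
stratified_folds <- function(y, folds, seed) {
  y <- factor(y)
  if (nlevels(y) < 2L) {
    stop("classification needs at least two classes", call. = FALSE)
  }
  folds <- as.integer(folds)
  if (folds < 2L) stop("`folds` must be at least 2", call. = FALSE)
  small <- table(y) < folds
  if (any(small)) {
    stop("class(es) ", paste(names(which(small)), collapse = ", "),
         " have fewer than ", folds,
         " observations; use fewer folds", call. = FALSE)
  }
  set.seed(seed)
  assign <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

# Kernel scale heuristic: median pairwise Euclidean distance among up to 64
# evenly spaced training rows (deterministic). Falls back to 1 when the
# median distance is 0 (e.g. duplicated rows).
kernel_scale <- function(x, max_rows = 64L) {
  n <- nrow(x)
  if (n > max_rows) {
    x <- x[unique(round(seq(1, n, length.out = max_rows))), , drop = FALSE]
  }
  ks <- stats::median(stats::dist(x))
  if (!is.finite(ks) || ks <= 0) 1 else ks
}

# Column-wise standardization with training statistics; zero-variance
# columns get unit scale. Returns the transformed train and test matrices.
standardize_pair <- function(x_train, x_test) {
  n <- nrow(x_train)
  mu <- colMeans(x_train)
  v <- (colSums(x_train^2) - n * mu^2) / (n - 1)
  sdv <- sqrt(pmax(v, 0))
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  ctr <- function(m) {
    (m - matrix(mu, nrow(m), length(mu), byrow = TRUE)) /
      matrix(sdv, nrow(m), length(sdv), byrow = TRUE)
  }
  list(train = ctr(x_train), test = ctr(x_test))
}

# Fit a cubic SVM on standardized training data and predict the test rows.
# Standardization statistics come from the training fold only. Kernel:
# (gamma <u, v> + 1)^3 with gamma = 1 / kernel_scale^2, box constraint 1,
# one-vs-one multi-class coding (libsvm's native scheme).
cubic_svm_predict <- function(x_train, y_train, x_test) {
  std <- standardize_pair(x_train, x_test)
  ks <- kernel_scale(std$train)
  fit <- e1071::svm(std$train, y_train, kernel = "polynomial", degree = 3,
                    gamma = 1 / ks^2, coef0 = 1, cost = 1, scale = FALSE)
  stats::predict(fit, std$test)
}

# Out-of-fold predictions for a given fold assignment.
svm_oof_predict <- function(x, y, fold_id) {
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    pred[te] <- cubic_svm_predict(x[!te, , drop = FALSE], y[!te],
                                  x[te, , drop = FALSE])
  }
  pred
}

#' Confusion-matrix classification metrics
#'
#' Computes the five evaluation metrics from a confusion matrix with truth
#' in rows and predictions in columns: overall accuracy (trace over total),
#' average (macro) recall, average (macro) precision, the F1-score as the
#' harmonic mean of the two macro averages, and the geometric mean of the
#' per-class recalls (an imbalance-robust summary reported alongside the
#' others). A class never predicted contributes precision 0.
#'
#' For balanced classes, accuracy equals the macro average recall.
#'
#' @param confusion Square nonnegative integer matrix (rows = truth,
#'   columns = predicted, matching order) with at least one observation.
#' @return Named numeric vector `accuracy`, `average_recall`,
#'   `average_precision`, `f1_score`, `geometric_mean`, all in \[0, 1\].
#' @examples
#' classification_metrics(matrix(c(45, 10, 5, 40), 2))
#' @export
classification_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm) || any(cm < 0) || sum(cm) < 1) {
    stop("`confusion` must be a square nonnegative matrix with at least one count",
         call. = FALSE)
  }
  tp <- diag(cm)
  truth <- rowSums(cm)
  predicted <- colSums(cm)
  recall <- ifelse(truth > 0, tp / truth, 0)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  ar <- mean(recall)
  ap <- mean(precision)
  f1 <- if (ap + ar > 0) 2 * ap * ar / (ap + ar) else 0
  c(accuracy = sum(tp) / sum(cm),
    average_recall = ar,
    average_precision = ap,
    f1_score = f1,
    geometric_mean = exp(mean(log(pmax(recall, .Machine$double.xmin)))) *
      (min(recall) > 0))
}

#' Cubic-SVM cross-validated evaluation
#'
#' Evaluates a feature matrix with a degree-3 polynomial-kernel SVM
#' (one-vs-one multi-class coding, box constraint 1) under stratified,
#' seeded k-fold cross-validation. Within each fold, features are
#' standardized with training-fold statistics only and the kernel scale is
#' set by the median-pairwise-distance heuristic on the training rows. The
#' out-of-fold predictions are accumulated into a single confusion matrix
#' from which the metrics are computed.
#'
#' The procedure is deterministic given the seed.
#'
#' @param x Numeric matrix, observations x features, or a
#'   `"feature_matrix"` object (in which case `y` is taken from it).
#' @param y Class labels (factor or coercible); one per row of `x`.
#' @param folds Number of folds (default 10). Every class needs at least
#'   `folds` observations.
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `"svm_cv_report"`: list with `confusion`
#'   (truth x predicted table), `metrics` (see
#'   [classification_metrics()]), `fold_assignment`, `predictions`
#'   (out-of-fold, one per observation) and `seed`.
#' @export
cubic_svm_cv <- function(x, y = NULL, folds = 10, seed = 1) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$y
    x <- x$x
  }
  y <- factor(y)
  if (nrow(x) != length(y)) {
    stop("`x` rows and `y` length differ", call. = FALSE)
  }
  fold_id <- stratified_folds(y, folds, seed)
  pred <- svm_oof_predict(x, y, fold_id)
  confusion <- table(truth = y, predicted = pred)
  structure(
    list(confusion = confusion,
         metrics = classification_metrics(confusion),
         fold_assignment = fold_id,
         predictions = pred,
         folds = as.integer(folds),
         seed = seed),
    class = "svm_cv_report"
  )
}

#' Write an evaluation report to a structured text file
#'
#' Serializes an `"svm_cv_report"` to a plain-text audit file: seed and fold
#' count, the five metrics, the confusion matrix, and the per-observation
#' fold assignment and out-of-fold prediction.
#'
#' @param report An `"svm_cv_report"` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "svm_cv_report"))
  con <- file(path, "w")
  on.exit(close(con))
  cm <- as.matrix(report$confusion)
  writeLines(c(
    sprintf("seed\t%d", report$seed),
    sprintf("folds\t%d", report$folds),
    sprintf("%s\t%.10g", names(report$metrics), report$metrics),
    sprintf("confusion_classes\t%s", paste(rownames(cm), collapse = ",")),
    sprintf("confusion_row\t%s",
            apply(cm, 1, function(r) paste(r, collapse = ","))),
    sprintf("fold_assignment\t%s",
            paste(report$fold_assignment, collapse = ",")),
    sprintf("predictions\t%s",
            paste(as.character(report$predictions), collapse = ","))
  ), con)
  invisible(path)
}

#' @export
print.svm_cv_report <- function(x, digits = 4, ...) {
  cat(sprintf("Cubic-SVM %d-fold cross-validation (seed %d)\n",
              x$folds, x$seed))
  print(x$confusion)
  m <- round(x$metrics, digits)
  cat(sprintf("  accuracy %.4g | avg recall %.4g | avg precision %.4g | F1 %.4g | g-mean %.4g\n",
              m[1], m[2], m[3], m[4], m[5]))
  invisible(x)
}
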