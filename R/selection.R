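#' Multi-class ReliefF feature weights
#'
#' Standard ReliefF: every observation is visited; its `k_neighbors`
#' nearest same-class neighbours ("hits") decrease each feature's weight by
#' the feature-wise normalized difference, and for every other class the
#' `k_neighbors` nearest members ("misses") increase it, weighted by that
#' class's prior over one minus the prior of the observation's own class.
#' Distances are Manhattan on features min-max scaled to \[0, 1\]
#' (neighbours are weighted uniformly). Weights can be negative —
#' negative-weight features behave like noise — and a constant feature gets
#' weight 0 by convention.
#'
#' @param x Numeric matrix, observations x features.
#' @param y Class labels, at least two classes.
#' @param k_neighbors Hits/misses per class (default 10); classes with
#'   fewer members contribute all they have.
#' @return Numeric vector of one weight per feature.
#' @export
relieff_weights <- function(x, y, k_neighbors = 10) {
  y <- factor(y)
  if (nlevels(y) < 2L) {
    stop("ReliefF needs at least two classes", call. = FALSE)
  }
  n <- nrow(x)
  p <- ncol(x)
  if (n != length(y)) stop("`x` rows and `y` length differ", call. = FALSE)
  if (min(table(y)) < 2L) {
    stop("every class needs at least 2 observations", call. = FALSE)
  }
  # min-max scale; constant columns become all-zero (weight 0 falls out)
  lo <- apply(x, 2, min)
  span <- apply(x, 2, max) - lo
  keepable <- span > 0
  xs <- x
  xs[, keepable] <- sweep(sweep(x[, keepable, drop = FALSE], 2,
                                lo[keepable]), 2, span[keepable], "/")
  xs[, !keepable] <- 0
  d <- as.matrix(stats::dist(xs, method = "manhattan"))
  priors <- as.numeric(table(y)) / n
  names(priors) <- levels(y)
  w <- numeric(p)
  for (i in seq_len(n)) {
    ci <- as.character(y[i])
    same <- which(y == y[i])
    same <- same[same != i]
    hits <- same[order(d[i, same])][seq_len(min(k_neighbors, length(same)))]
    hit_diff <- abs(xs[hits, , drop = FALSE] -
                      matrix(xs[i, ], length(hits), p, byrow = TRUE))
    w <- w - colSums(hit_diff) / (n * length(hits))
    for (cl in levels(y)[levels(y) != ci]) {
      other <- which(y == cl)
      miss <- other[order(d[i, other])][seq_len(min(k_neighbors, length(other)))]
      miss_diff <- abs(xs[miss, , drop = FALSE] -
                         matrix(xs[i, ], length(miss), p, byrow = TRUE))
      w <- w + priors[[cl]] / (1 - priors[[ci]]) *
        colSums(miss_diff) / (n * length(miss))
    }
  }
  unname(w)
}

#' Chi-square relevance scores of continuous features
#'
#' Each feature is discretized into `n_bins` equal-width bins over its
#' observed range, and the chi-square statistic of the bin x class
#' contingency table is returned (larger = stronger association with the
#' label). Empty bins are dropped from the table; a constant feature scores
#' 0. Scores are invariant to observation order.
#'
#' @param x Numeric matrix, observations x features.
#' @param y Class labels, at least two classes.
#' @param n_bins Number of equal-width bins (default 10).
#' @return Numeric vector of one score per feature.
#' @export
chi2_scores <- function(x, y, n_bins = 10) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop("chi2 needs at least two classes", call. = FALSE)
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 2L)
  n <- nrow(x)
  cls <- as.integer(y)
  n_cls <- nlevels(y)
  cls_tot <- tabulate(cls, n_cls)
  vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    lo <- min(v)
    span <- max(v) - lo
    if (span == 0) return(0)
    bin <- pmin(floor((v - lo) / span * n_bins) + 1L, n_bins)
    counts <- matrix(tabulate((cls - 1L) * n_bins + bin, n_bins * n_cls),
                     n_bins, n_cls)
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
    expected <- outer(rowSums(counts), cls_tot) / n
    sum((counts - expected)^2 / expected)
  }, numeric(1))
}

# Inclusive candidate sizes of the iterative sweep, step 1; the default
# range 100..1000 enumerates 901 candidates.
candidate_sizes <- function(size_range) {
  stopifnot(length(size_range) == 2L, size_range[1] <= size_range[2])
  seq.int(as.integer(size_range[1]), as.integer(size_range[2]))
}

#' RFIChi2 hybrid feature selection
#'
#' The two-stage selector: (1) ReliefF weights are computed and every
#' feature with a negative weight is pruned as redundant; (2) survivors are
#' ranked by chi-square score (ties broken by original column index) and,
#' for every candidate size `s` in `size_range` (step 1; the default
#' \[100, 1000\] gives 901 candidates), the top-`s` features are scored by
#' the misclassification rate of the cubic SVM under stratified k-fold
#' cross-validation. One seeded fold partition is drawn and reused for all
#' candidate sizes so the loss curve is comparable across sizes. The
#' loss-minimizing size wins, ties going to the smallest size.
#'
#' When fewer features survive pruning than the requested range allows, the
#' range is clipped to the survivor count (with a message).
#'
#' @param x Numeric matrix, observations x features, or a
#'   `"feature_matrix"` object.
#' @param y Class labels; taken from `x` when it is a feature matrix.
#' @param size_range Inclusive candidate-size interval, default
#'   `c(100, 1000)`.
#' @param folds Cross-validation folds for the loss (default 10).
#' @param seed Integer seed (fold partition).
#' @param k_neighbors ReliefF neighbours (default 10).
#' @param n_bins Chi-square discretization bins (default 10).
#' @return An object of class `"rfichi2"`: list with `relieff_weights`,
#'   `kept_after_relieff` (indices with nonnegative weight), `chi2_order`
#'   (survivors ranked by score), `sizes`, `loss_curve` (misclassification
#'   per candidate size), `chosen_size`, `selected` (ordered column
#'   indices) and `seed`.
#' @export
rfichi2_select <- function(x, y = NULL, size_range = c(100, 1000),
                           folds = 10, seed = 1, k_neighbors = 10,
                           n_bins = 10) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- x$y
    x <- x$x
  }
  y <- factor(y)
  w <- relieff_weights(x, y, k_neighbors)
  kept <- which(w >= 0)
  if (length(kept) < 2L) {
    stop("only ", length(kept), " features survive ReliefF pruning; ",
         "cannot rank a candidate set", call. = FALSE)
  }
  scores <- chi2_scores(x[, kept, drop = FALSE], y, n_bins)
  ord <- kept[order(-scores, kept)]
  sizes <- candidate_sizes(size_range)
  if (length(kept) < max(sizes)) {
    message("only ", length(kept), " features survive ReliefF pruning; ",
            "clipping the candidate range to it")
    sizes <- sizes[sizes <= length(kept)]
    if (length(sizes) == 0L) sizes <- length(kept)
  }
  fold_id <- stratified_folds(y, folds, seed)
  loss <- vapply(sizes, function(s) {
    pred <- svm_oof_predict(x[, ord[seq_len(s)], drop = FALSE], y, fold_id)
    mean(pred != y)
  }, numeric(1))
  best <- sizes[which.min(loss)]   # sizes ascend: ties go to the smallest
  structure(
    list(relieff_weights = w,
         kept_after_relieff = kept,
         chi2_order = ord,
         sizes = sizes,
         loss_curve = stats::setNames(loss, sizes),
         chosen_size = best,
         selected = ord[seq_len(best)],
         folds = as.integer(folds),
         seed = seed),
    class = "rfichi2"
  )
}

#' @export
print.rfichi2 <- function(x, ...) {
  cat("RFIChi2 selection\n")
  cat(sprintf("  %d of %d features survived ReliefF pruning\n",
              length(x$kept_after_relieff), length(x$relieff_weights)))
  cat(sprintf("  swept %d candidate sizes in [%d, %d]; chose %d features (CV loss %.4f)\n",
              length(x$sizes), min(x$sizes), max(x$sizes), x$chosen_size,
              min(x$loss_curve)))
  invisible(x)
}

#' Write an RFIChi2 selection audit file
#'
#' Serializes a selection result to a plain-text audit file: the chosen
#' size, the selected indices in rank order, the ReliefF weights and the
#' loss curve.
#'
#' @param sel An `"rfichi2"` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_selection <- function(sel, path) {
  stopifnot(inherits(sel, "rfichi2"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("chosen_size\t%d", sel$chosen_size),
    sprintf("seed\t%d", sel$seed),
    sprintf("selected\t%s", paste(sel$selected, collapse = ",")),
    sprintf("kept_after_relieff\t%s",
            paste(sel$kept_after_relieff, collapse = ",")),
    sprintf("relieff_weights\t%s",
            paste(format(sel$relieff_weights, digits = 10), collapse = ",")),
    sprintf("loss_curve\t%s",
            paste(sprintf("%d:%.6f", sel$sizes, sel$loss_curve),
                  collapse = ","))
  ), con)
  invisible(path)
}
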