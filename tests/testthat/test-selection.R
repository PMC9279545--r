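test_that("ReliefF rewards label-aligned features and zeroes constants", {
  set.seed(51)
  n <- 200
  y <- factor(rep(1:2, each = n / 2))
  x <- cbind(
    as.integer(y),            # perfectly class-aligned
    rnorm(n),                 # noise
    rep(3, n),                # constant
    rnorm(n)                  # noise (duplicated below)
  )
  x <- cbind(x, x[, 4])       # duplicate column
  w <- relieff_weights(x, y, k_neighbors = 10)
  expect_identical(which.max(w), 1L)
  expect_gt(w[1], 0)
  expect_identical(w[3], 0)
  expect_equal(w[4], w[5])    # duplicated features weigh the same
  expect_error(relieff_weights(x, factor(rep(1, n))), "two classes")
})

test_that("ReliefF weights of pure-noise features hover near zero", {
  set.seed(52)
  n <- 500
  y <- factor(rep(1:2, each = n / 2))
  x <- matrix(rnorm(n * 30), n)
  w <- relieff_weights(x, y, k_neighbors = 10)
  expect_lt(max(abs(w)), 0.05)
  # roughly symmetric sign distribution
  expect_gt(mean(w < 0), 0.2)
  expect_lt(mean(w < 0), 0.8)
})

test_that("chi-square scores detect association and ignore row order", {
  set.seed(53)
  n <- 100
  y <- factor(rep(1:2, each = n / 2))
  x <- cbind(as.integer(y) + rnorm(n, 0, 0.01), rnorm(n), rep(1, n))
  s <- chi2_scores(x, y, n_bins = 10)
  expect_identical(which.max(s), 1L)
  expect_identical(s[3], 0)
  perm <- sample(n)
  expect_equal(chi2_scores(x[perm, ], y[perm]), s)
})

test_that("chi-square scores of independent noise follow the null mean", {
  set.seed(54)
  n <- 100
  y <- factor(rep(1:2, each = n / 2))
  x <- matrix(runif(n * 300), n)
  s <- chi2_scores(x, y, n_bins = 10)
  # null: chi-square with (10 - 1) * (2 - 1) = 9 df, mean 9
  expect_gt(mean(s), 7.5)
  expect_lt(mean(s), 10.5)
})

test_that("RFIChi2 prunes negatives, ranks by chi2 and sweeps nested sets", {
  set.seed(55)
  pl <- make_planted(n = 100, n_informative = 20, n_noise = 400, shift = 2,
                     seed = 56)
  sel <- rfichi2_select(pl$x, pl$y, size_range = c(10, 60), folds = 5,
                        seed = 57)
  expect_true(all(sel$selected %in% sel$kept_after_relieff))
  expect_true(all(sel$relieff_weights[sel$selected] >= 0))
  expect_length(sel$selected, sel$chosen_size)
  expect_identical(names(which.min(sel$loss_curve)),
                   as.character(sel$chosen_size))
  expect_length(sel$loss_curve, 51)
  # nested top-s sets
  expect_identical(sel$chi2_order[1:10], sel$chi2_order[1:20][1:10])
  # most planted features should rank into the selected set
  expect_gte(mean(pl$informative %in% sel$selected), 0.5)

  # internal consistency: re-running the classifier on the returned set
  # with the same seed reproduces the loss-curve minimum
  fold_id <- ledpatnet:::stratified_folds(pl$y, 5, 57)
  pred <- ledpatnet:::svm_oof_predict(pl$x[, sel$selected, drop = FALSE],
                                      pl$y, fold_id)
  expect_equal(unname(min(sel$loss_curve)), mean(pred != pl$y))
})

test_that("selection is reproducible and clips an infeasible range", {
  set.seed(58)
  pl <- make_planted(n = 60, n_informative = 10, n_noise = 80, shift = 2,
                     seed = 59)
  s1 <- rfichi2_select(pl$x, pl$y, size_range = c(5, 25), folds = 5, seed = 3)
  s2 <- rfichi2_select(pl$x, pl$y, size_range = c(5, 25), folds = 5, seed = 3)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$loss_curve, s2$loss_curve)

  # range wider than the survivor count gets clipped with a message
  expect_message(
    s3 <- rfichi2_select(pl$x, pl$y, size_range = c(5, 10000), folds = 5,
                         seed = 3),
    "clipping"
  )
  expect_lte(max(s3$sizes), length(s3$kept_after_relieff))

  stem <- file.path(tempdir(), "sel_audit.tsv")
  write_selection(s1, stem)
  lines <- readLines(stem)
  expect_match(lines[1], "^chosen_size\t")
  expect_match(lines[3], paste(s1$selected, collapse = ","), fixed = TRUE)
})
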