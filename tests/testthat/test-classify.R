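test_that("metrics match the hand-evaluated 2-class example", {
  cm <- matrix(c(45, 10, 5, 40), 2)   # truth rows: (45,5) / (10,40)
  m <- classification_metrics(cm)
  expect_equal(m[["accuracy"]], 0.85)
  expect_equal(m[["average_recall"]], 0.85)
  expect_equal(m[["average_precision"]], (45 / 55 + 40 / 45) / 2)
  ap <- (45 / 55 + 40 / 45) / 2
  expect_equal(m[["f1_score"]], 2 * ap * 0.85 / (ap + 0.85))
  expect_equal(m[["geometric_mean"]], sqrt(0.9 * 0.8))
})

test_that("a diagonal confusion gives all-ones metrics; permutation leaves them fixed", {
  m <- classification_metrics(diag(c(7, 3, 5)))
  expect_equal(unname(m), rep(1, 5))

  cm <- matrix(c(30, 4, 2, 3, 25, 6, 1, 5, 24), 3)
  perm <- c(2, 3, 1)
  expect_equal(classification_metrics(cm[perm, perm]),
               classification_metrics(cm))
  # a never-predicted class contributes precision 0
  cm0 <- matrix(c(10, 5, 0, 0), 2)
  m0 <- classification_metrics(cm0)
  expect_equal(m0[["average_precision"]], (10 / 15 + 0) / 2)
  expect_equal(m0[["geometric_mean"]], 0)
})

test_that("well-separated Gaussian classes are classified nearly perfectly", {
  blobs <- make_blobs(100, rbind(c(0, 0, 0), c(6, 6, 6)), sd = 1, seed = 41)
  rep <- cubic_svm_cv(blobs$x, blobs$y, folds = 10, seed = 1)
  expect_gte(rep$metrics[["accuracy"]], 0.99)
  expect_equal(sum(rep$confusion), 200)
  # balanced classes: accuracy equals macro average recall exactly
  expect_equal(rep$metrics[["accuracy"]], rep$metrics[["average_recall"]])
})

test_that("permuted labels score at chance level", {
  blobs <- make_blobs(100, rbind(c(0, 0, 0), c(6, 6, 6)), sd = 1, seed = 42)
  set.seed(99)
  y_perm <- sample(blobs$y)
  rep <- cubic_svm_cv(blobs$x, y_perm, folds = 10, seed = 2)
  expect_gte(rep$metrics[["accuracy"]], 0.35)
  expect_lte(rep$metrics[["accuracy"]], 0.65)
})

test_that("evaluation is deterministic given the seed and stratified", {
  blobs <- make_blobs(30, rbind(c(0, 0), c(2, 2), c(-2, 2)), sd = 1.5,
                      seed = 43)
  r1 <- cubic_svm_cv(blobs$x, blobs$y, folds = 5, seed = 7)
  r2 <- cubic_svm_cv(blobs$x, blobs$y, folds = 5, seed = 7)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$fold_assignment, r2$fold_assignment)
  expect_identical(r1$predictions, r2$predictions)
  # stratification: every fold holds each class in proportion
  for (f in 1:5) {
    expect_equal(as.integer(table(blobs$y[r1$fold_assignment == f])),
                 rep(6L, 3))
  }
  # too few observations per class for the fold count
  expect_error(cubic_svm_cv(blobs$x[1:36, ], blobs$y[1:36], folds = 10),
               "fewer folds")
  # a single-class subset is rejected outright
  expect_error(cubic_svm_cv(blobs$x[1:12, ], blobs$y[1:12], folds = 10),
               "two classes")

  # the report serializes to a readable audit file
  path <- file.path(tempdir(), "report.tsv")
  write_report(r1, path)
  lines <- readLines(path)
  expect_match(lines[1], "^seed\t7$")
  expect_match(lines, "^accuracy\t", all = FALSE)
  expect_length(grep("^confusion_row\t", lines), 3)
})
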