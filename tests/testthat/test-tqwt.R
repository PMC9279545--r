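test_that("parameter validation enforces the oversampling construction", {
  p <- tqwt_params(2, 3, 17)
  expect_equal(p$beta, 2 / 3)
  expect_equal(p$alpha, 1 - (2 / 3) / 3)
  expect_gt(p$alpha + p$beta, 1)
  expect_error(tqwt_params(0.5, 3, 17), "q_factor")
  expect_error(tqwt_params(2, 1, 17), "redundancy")
  expect_error(tqwt_params(2, 3, 0), "levels")
})

test_that("decomposition yields J + 1 sub-bands of non-increasing length", {
  sb <- tqwt_decompose(rnorm(7650), tqwt_params(2, 3, 17))
  expect_length(sb$bands, 18)
  lens <- vapply(sb$bands[1:17], length, 0L)
  expect_true(all(diff(lens) <= 0))
  expect_true(all(lens >= 1))

  sb2 <- tqwt_decompose(rnorm(400), tqwt_params(1, 3, 4))
  expect_length(sb2$bands, 5)
})

test_that("a zero signal decomposes into all-zero sub-bands", {
  sb <- tqwt_decompose(numeric(512), tqwt_params(2, 3, 6))
  for (b in sb$bands) expect_equal(max(abs(b)), 0)
})

test_that("decompose/reconstruct round trip is exact over a parameter grid", {
  set.seed(3)
  grid <- list(c(1, 3, 4, 512), c(2, 3, 17, 7650), c(3, 4, 8, 1024),
               c(2, 3, 5, 200), c(5, 2, 6, 2048))
  for (g in grid) {
    x <- rnorm(g[4])
    sb <- tqwt_decompose(x, tqwt_params(g[1], g[2], g[3]))
    y <- tqwt_reconstruct(sb)
    expect_lt(max(abs(y - x)) / max(abs(x)), 1e-8)
  }
})

test_that("odd-length signals are padded, recorded, and recovered exactly", {
  set.seed(4)
  x <- rnorm(333)
  sb <- tqwt_decompose(x, tqwt_params(2, 3, 4))
  expect_true(sb$padded)
  expect_identical(sb$original_length, 333L)
  y <- tqwt_reconstruct(sb)
  expect_length(y, 333)
  expect_lt(max(abs(y - x)), 1e-10)
})

test_that("an impulse round-trips and the transform is linear", {
  n <- 256
  p <- tqwt_params(2, 3, 4)
  imp <- c(1, numeric(n - 1))
  expect_lt(max(abs(tqwt_reconstruct(tqwt_decompose(imp, p)) - imp)), 1e-12)

  set.seed(6)
  x <- rnorm(n); y <- rnorm(n)
  a <- 2.5; b <- -1.25
  sxy <- tqwt_decompose(a * x + b * y, p)
  sx <- tqwt_decompose(x, p)
  sy <- tqwt_decompose(y, p)
  for (j in seq_along(sxy$bands)) {
    expect_equal(sxy$bands[[j]], a * sx$bands[[j]] + b * sy$bands[[j]],
                 tolerance = 1e-10)
  }
})

test_that("total sub-band energy stays within a sane band of signal energy", {
  set.seed(8)
  x <- rnorm(2048)
  for (r in c(2, 3, 5)) {
    sb <- tqwt_decompose(x, tqwt_params(2, r, 8))
    e <- sum(vapply(sb$bands, function(b) sum(b^2), 0)) / sum(x^2)
    expect_gt(e, 0.5)
    expect_lt(e, 2 * r)
  }
})

test_that("max_levels guards the feasible depth", {
  expect_gte(max_levels(7650, tqwt_params(2, 3, 17)), 17)
  expect_lt(max_levels(16, tqwt_params(2, 3, 1)), 17)
  expect_identical(max_levels(0, tqwt_params()), 0L)
  # the reported depth is actually feasible and one more is not
  for (n in c(64, 500, 7650)) {
    p0 <- tqwt_params(2, 3, 1)
    jm <- max_levels(n, p0)
    expect_silent(tqwt_decompose(rnorm(n), tqwt_params(2, 3, jm)))
    expect_error(tqwt_decompose(rnorm(n), tqwt_params(2, 3, jm + 1)),
                 "maximum feasible depth")
  }
})

test_that("inconsistent band lengths are rejected at reconstruction", {
  sb <- tqwt_decompose(rnorm(512), tqwt_params(2, 3, 5))
  sb$bands[[2]] <- sb$bands[[2]][-1]
  expect_error(tqwt_reconstruct(sb), "parameters imply")
})
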