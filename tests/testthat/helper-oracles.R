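# Independent oracles and data builders shared by the tests. The oracles
# deliberately re-read the definitions literally (per-window loops, direct
# formulas) instead of reusing the package's vectorized paths.

# Literal per-window Led-Pattern: block division, signum comparison against
# the S-box target, LSB-first byte packing, histogram accumulation.
oracle_led_pattern <- function(signal, sbox = led_sbox()) {
  n <- length(signal)
  hl <- integer(256)
  hr <- integer(256)
  for (i in 1:(n - 15)) {
    blc <- signal[i:(i + 15)]
    bits <- integer(16)
    for (k in 1:16) {
      bits[k] <- if (blc[k] - blc[sbox[k] + 1] >= 0) 1L else 0L
    }
    left <- sum(bits[1:8] * 2^(0:7))
    right <- sum(bits[9:16] * 2^(0:7))
    hl[left + 1] <- hl[left + 1] + 1L
    hr[right + 1] <- hr[right + 1] + 1L
  }
  c(hl, hr)
}

# Gaussian class blobs: n_per_class observations per class, class centers
# given as a classes x p matrix.
make_blobs <- function(n_per_class, centers, sd = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  p <- ncol(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(c) {
    matrix(rnorm(n_per_class * p, 0, sd), n_per_class) +
      matrix(centers[c, ], n_per_class, p, byrow = TRUE)
  }))
  list(x = x, y = factor(rep(seq_len(k), each = n_per_class)))
}

# Planted-feature data: the first n_informative columns carry a
# class-dependent mean shift, the remaining n_noise columns are pure noise.
make_planted <- function(n = 100, n_informative = 50, n_noise = 3000,
                         shift = 2, seed = 1) {
  set.seed(seed)
  y <- factor(rep(1:2, length.out = n))
  x <- matrix(rnorm(n * (n_informative + n_noise)), n)
  signs <- rep_len(c(1, -1), n_informative)
  for (j in seq_len(n_informative)) {
    x[, j] <- x[, j] + shift * signs[j] * (as.integer(y) - 1)
  }
  list(x = x, y = y, informative = seq_len(n_informative))
}
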