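#' The 4-bit S-box of the LED block cipher
#'
#' Returns the substitution box used as the nonlinear comparison pattern of
#' the Led-Pattern descriptor. The LED cipher shares this S-box with the
#' PRESENT cipher; it is a fixed bijection on \{0, ..., 15\}. Entry `k`
#' (0-based input `k - 1` in 1-based R indexing) names the 0-based window
#' position that window position `k` is compared against.
#'
#' @return An integer vector of length 16 of class `"led_sbox"`: a
#'   permutation of `0:15`.
#' @examples
#' s <- led_sbox()
#' s[1]   # 12: window position 1 is compared against position 13
#' sort(s)
#' @export
led_sbox <- function() {
  structure(
    c(12L, 5L, 6L, 11L, 9L, 0L, 10L, 13L, 3L, 14L, 15L, 8L, 4L, 7L, 1L, 2L),
    class = "led_sbox"
  )
}

# Validate an S-box: 16 integers forming a permutation of 0..15.
check_sbox <- function(sbox) {
  s <- as.integer(sbox)
  if (length(s) != 16L || anyNA(s) || !identical(sort(s), 0:15)) {
    stop("`sbox` must be a permutation of the integers 0..15 (length 16)",
         call. = FALSE)
  }
  s
}

#' Generate the 16 comparison bits of one Led-Pattern window
#'
#' For a 16-sample window `v`, bit `k` is 1 when
#' `v[k] - v[sbox[k] + 1] >= 0` and 0 otherwise (two-argument signum with
#' ties mapping to 1). The S-box entry is a 0-based position, hence the
#' `+ 1` under R's 1-based indexing.
#'
#' @param block Numeric vector of length 16 (one overlapping window).
#' @param sbox An S-box as returned by [led_sbox()].
#' @return Integer vector of 16 bits (0/1).
#' @examples
#' extract_bits(1:16)          # bits against the LED S-box
#' extract_bits(rep(0, 16))    # constant window: all ties, all ones
#' @export
extract_bits <- function(block, sbox = led_sbox()) {
  if (!is.numeric(block) || length(block) != 16L || anyNA(block)) {
    stop("`block` must be a numeric vector of exactly 16 finite values",
         call. = FALSE)
  }
  s <- check_sbox(sbox)
  as.integer(block - block[s + 1L] >= 0)
}

#' Pack 16 bits into the left and right 8-bit codes
#'
#' Bits 1..8 form the left code and bits 9..16 the right code, bit 1 (and
#' bit 9) being the least-significant bit: `code = sum(bits * 2^(0:7))`.
#'
#' @param bits Integer/logical vector of 16 binary values.
#' @return Named integer vector `c(left =, right =)`, each in 0..255.
#' @examples
#' encode_codes(rep(1, 16))  # c(left = 255, right = 255)
#' @export
encode_codes <- function(bits) {
  b <- as.integer(bits)
  if (length(b) != 16L || anyNA(b) || any(b != 0L & b != 1L)) {
    stop("`bits` must be 16 binary (0/1) values", call. = FALSE)
  }
  w <- 2L^(0:7)
  c(left = as.integer(sum(b[1:8] * w)), right = as.integer(sum(b[9:16] * w)))
}

#' Led-Pattern textural features of a one-dimensional signal
#'
#' Slides a 16-sample overlapping window over the signal (`L - 15` windows
#' for a signal of length `L`). In each window the S-box-guided signum
#' comparisons yield 16 bits, packed into an 8-bit left and an 8-bit right
#' code; the two code streams are histogrammed over 256 bins each and the
#' histograms concatenated (left first) into 512 features.
#'
#' The codes depend only on the signs of within-window differences, so the
#' features are invariant to adding a constant to the signal and to
#' multiplying it by a positive constant.
#'
#' @param signal Numeric vector, length at least 16.
#' @param sbox An S-box as returned by [led_sbox()].
#' @return An object of class `"led_pattern"`: a list with `hist_left` and
#'   `hist_right` (256 nonnegative integer counts each, bin `j` counting
#'   code `j - 1`), `features` (their 512-element concatenation) and
#'   `n_blocks` (`L - 15`). Each histogram sums to `n_blocks`.
#' @examples
#' lp <- led_pattern(sin(seq_len(200)))
#' length(lp$features)   # 512
#' sum(lp$hist_left)     # 185 = 200 - 15
#' @export
led_pattern <- function(signal, sbox = led_sbox()) {
  if (!is.numeric(signal) || anyNA(signal)) {
    stop("`signal` must be a numeric vector without missing values",
         call. = FALSE)
  }
  n <- length(signal)
  if (n < 16L) {
    stop("`signal` has ", n, " samples; Led-Pattern needs at least 16",
         call. = FALSE)
  }
  s <- check_sbox(sbox)
  nb <- n - 15L
  # bits[i, k]: comparison bit k of the window starting at sample i
  bits <- matrix(FALSE, nb, 16L)
  for (k in 1:16) {
    tgt <- s[k] + 1L
    bits[, k] <- signal[k:(k + nb - 1L)] - signal[tgt:(tgt + nb - 1L)] >= 0
  }
  w <- 2^(0:7)
  left <- as.integer(bits[, 1:8, drop = FALSE] %*% w)
  right <- as.integer(bits[, 9:16, drop = FALSE] %*% w)
  hist_left <- tabulate(left + 1L, nbins = 256L)
  hist_right <- tabulate(right + 1L, nbins = 256L)
  structure(
    list(hist_left = hist_left, hist_right = hist_right,
         features = c(hist_left, hist_right), n_blocks = nb),
    class = "led_pattern"
  )
}

#' @export
print.led_pattern <- function(x, ...) {
  cat("Led-Pattern features: 512 histogram counts over", x$n_blocks,
      "overlapping 16-sample windows\n")
  nz <- sum(x$features > 0)
  cat("  occupied bins:", nz, "of 512\n")
  invisible(x)
}
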