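#' Fourteen statistical moments of a signal
#'
#' Computes the fixed 14-component statistical descriptor used alongside the
#' textural features: mean, sample standard deviation, sum, an entropy-like
#' statistic of the RMS-normalised samples, mean absolute first difference,
#' bias-corrected skewness and kurtosis, median, minimum, maximum, energy,
#' root mean square, range, and maximum minus mean.
#'
#' Conventions (each isolated here so it can be audited or replaced):
#' \itemize{
#'   \item Entropy term: with `p_i = x_i / RMS(x)`, the statistic is
#'     `-sum(p_i * log(p_i))` over the samples with `p_i > 0`; samples with
#'     `p_i <= 0` contribute 0 (the logarithm is undefined there). Natural
#'     logarithm. A zero signal has RMS 0 and the term is defined as 0.
#'   \item Median: element `ceiling(M/2)` of the ascending-sorted signal —
#'     for even lengths the lower-middle element, no interpolation.
#'   \item Mean absolute first difference divides the `M - 1` absolute
#'     differences by `M`.
#'   \item Skewness/kurtosis are the bias-corrected sample forms
#'     (`sqrt(M(M-1))/(M-2) * m3/m2^1.5` and the analogous excess-kurtosis
#'     correction re-centred to 3); a zero-variance signal returns 0 for
#'     both.
#' }
#'
#' @param signal Numeric vector of length at least 4 (the corrected
#'   kurtosis needs more than 3 samples).
#' @return Named numeric vector of length 14, in the order listed above.
#' @examples
#' stat_moments(c(1, 2, 3, 4))
#' @export
stat_moments <- function(signal) {
  if (!is.numeric(signal) || anyNA(signal)) {
    stop("`signal` must be a numeric vector without missing values",
         call. = FALSE)
  }
  m <- length(signal)
  if (m < 4L) {
    stop("`signal` has ", m, " samples; the moment vector needs at least 4",
         call. = FALSE)
  }
  mu <- mean(signal)
  d <- signal - mu
  m2 <- mean(d^2)
  rms <- sqrt(mean(signal^2))
  if (rms > 0) {
    p <- signal / rms
    pos <- p > 0
    entropy <- -sum(p[pos] * log(p[pos]))
  } else {
    entropy <- 0
  }
  if (m2 > 0) {
    skew <- sqrt(m * (m - 1)) / (m - 2) * mean(d^3) / m2^1.5
    kurt <- (m - 1) / ((m - 2) * (m - 3)) *
      ((m + 1) * (mean(d^4) / m2^2 - 3) + 6)
  } else {
    skew <- 0
    kurt <- 0
  }
  mn <- min(signal)
  mx <- max(signal)
  c(
    mean = mu,
    sd = sqrt(sum(d^2) / (m - 1)),
    sum = sum(signal),
    entropy = entropy,
    mean_abs_diff = sum(abs(diff(signal))) / m,
    skewness = skew,
    kurtosis = kurt,
    median = sort(signal)[ceiling(m / 2)],
    min = mn,
    max = mx,
    energy = sum(signal^2),
    rms = rms,
    range = mx - mn,
    max_minus_mean = mx - mu
  )
}
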