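#' Split a recording into fixed-length non-overlapping frames
#'
#' @param signal Numeric vector (one channel's full recording).
#' @param frame_length Samples per frame; default 7650, i.e. roughly one
#'   minute at 128 Hz. Trailing samples that do not fill a frame are
#'   discarded.
#' @return A list of numeric vectors of length `frame_length`
#'   (`floor(length(signal) / frame_length)` of them). A recording shorter
#'   than one frame gives an empty list with a warning.
#' @examples
#' length(segment_frames(rnorm(38252), 7650))   # 5 (2 samples dropped)
#' @export
segment_frames <- function(signal, frame_length = 7650) {
  frame_length <- as.integer(frame_length)
  if (is.na(frame_length) || frame_length < 16L) {
    stop("`frame_length` must be an integer >= 16", call. = FALSE)
  }
  n <- length(signal)
  k <- n %/% frame_length
  if (k == 0L) {
    warning("signal of length ", n, " is shorter than one frame (",
            frame_length, " samples); returning no frames", call. = FALSE)
    return(list())
  }
  lapply(seq_len(k), function(i) {
    signal[((i - 1L) * frame_length + 1L):(i * frame_length)]
  })
}

#' Fused 540-feature descriptor of one signal
#'
#' Concatenates, for a single signal, the three per-signal feature groups:
#' positions 1-512 the Led-Pattern histogram features, 513-526 the 14
#' statistical moments of the signal, and 527-540 the 14 statistical
#' moments of the 512 Led-Pattern features themselves (statistics of the
#' texture histogram).
#'
#' @param signal Numeric vector, length at least 16.
#' @param sbox S-box for the textural descriptor (default [led_sbox()]).
#' @return Numeric vector of length 540.
#' @export
fused_features <- function(signal, sbox = led_sbox()) {
  lp <- led_pattern(signal, sbox)$features
  unname(c(lp, stat_moments(signal), stat_moments(lp)))
}

#' Multilevel fused feature vector of one EEG frame
#'
#' The full per-frame extractor: the frame is decomposed by TQWT into
#' `J + 1` sub-bands (18 with the default parameters) and the 540-element
#' fused descriptor is computed for the raw frame and for every sub-band,
#' in band order. Block `t` (1 = raw frame, `t > 1` = sub-band `t - 1`)
#' occupies positions `(t - 1) * 540 + 1` to `t * 540`; with the defaults
#' the result has `19 * 540 = 10260` features.
#'
#' @param frame Numeric vector (one frame of one channel).
#' @param params TQWT parameters, default `tqwt_params(2, 3, 17)`.
#' @param sbox S-box for the textural descriptor.
#' @return Numeric feature vector of length `(params$levels + 2) * 540`.
#' @examples
#' \donttest{
#' length(ledpatnet19_features(rnorm(7650)))   # 10260
#' }
#' @export
ledpatnet19_features <- function(frame, params = tqwt_params(),
                                 sbox = led_sbox()) {
  sb <- tqwt_decompose(frame, params)
  blocks <- c(list(frame), sb$bands)
  unlist(lapply(blocks, fused_features, sbox = sbox), use.names = FALSE)
}

#' Per-feature provenance of the multilevel fused vector
#'
#' @param levels TQWT level count J (default 17, giving 19 signal blocks).
#' @return A data frame with one row per feature: `column` (name used in
#'   feature matrices, `s<signal>_<kind>_<index>`), `signal` (0 = raw
#'   frame, 1..J+1 = sub-band), `kind` (`"textural"`, `"stat_signal"` or
#'   `"stat_textural"`) and `index` (position within the kind).
#' @export
feature_provenance <- function(levels = 17) {
  n_sig <- as.integer(levels) + 2L
  kind <- rep(c(rep("textural", 512), rep("stat_signal", 14),
                rep("stat_textural", 14)), n_sig)
  index <- rep(c(1:512, 1:14, 1:14), n_sig)
  signal <- rep(0:(n_sig - 1L), each = 540L)
  data.frame(
    column = sprintf("s%02d_%s_%03d", signal, kind, index),
    signal = signal, kind = kind, index = index,
    stringsAsFactors = FALSE
  )
}

#' Extract the feature matrix of a set of frames
#'
#' Runs [ledpatnet19_features()] on every frame and stacks the results into
#' an observations x features matrix with provenance-tagged column names.
#'
#' @param frames A list of numeric frames, or a matrix with one frame per
#'   row.
#' @param labels Class label per frame (coerced to factor).
#' @param params TQWT parameters.
#' @param sbox S-box for the textural descriptor.
#' @return An object of class `"feature_matrix"`: list with `x` (numeric
#'   matrix, 10260 columns under the defaults), `y` (factor) and
#'   `provenance` (see [feature_provenance()]).
#' @export
extract_feature_matrix <- function(frames, labels, params = tqwt_params(),
                                   sbox = led_sbox()) {
  if (is.matrix(frames)) {
    frames <- lapply(seq_len(nrow(frames)), function(i) frames[i, ])
  }
  y <- factor(labels)
  if (length(frames) != length(y)) {
    stop("`frames` and `labels` lengths differ (", length(frames), " vs ",
         length(y), ")", call. = FALSE)
  }
  x <- t(vapply(frames, ledpatnet19_features,
                numeric((params$levels + 2L) * 540L),
                params = params, sbox = sbox))
  prov <- feature_provenance(params$levels)
  colnames(x) <- prov$column
  structure(list(x = x, y = y, provenance = prov), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$x), "observations x", ncol(x$x), "features\n")
  cat("  classes:", paste(sprintf("%s (%d)", levels(x$y), table(x$y)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Write a feature matrix with its provenance sidecar
#'
#' Persists the matrix as `<path>.csv` (label column `class` first, then
#' one column per feature) and the per-column provenance as
#' `<path>_provenance.csv`.
#'
#' @param fm A `"feature_matrix"` object.
#' @param path Output path stem (no extension).
#' @return Invisibly, the two file paths written.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  main <- paste0(path, ".csv")
  side <- paste0(path, "_provenance.csv")
  df <- data.frame(class = fm$y, fm$x, check.names = FALSE)
  utils::write.csv(df, main, row.names = FALSE)
  utils::write.csv(fm$provenance, side, row.names = FALSE)
  invisible(c(main, side))
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path The path stem used when writing.
#' @return A `"feature_matrix"` object.
#' @export
read_feature_matrix <- function(path) {
  main <- paste0(path, ".csv")
  side <- paste0(path, "_provenance.csv")
  df <- utils::read.csv(main, check.names = FALSE)
  prov <- utils::read.csv(side, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  structure(list(x = x, y = factor(df$class), provenance = prov),
            class = "feature_matrix")
}
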