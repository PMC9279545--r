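#' EMOTIV EPOC channel names
#'
#' The 14 electrode names of the EMOTIV EPOC/EPOC+ headset, in the
#' conventional order.
#' @return Character vector of length 14.
#' @export
emotiv_channels <- function() {
  c("AF3", "AF4", "F3", "F4", "F7", "F8", "FC5", "FC6",
    "O1", "O2", "P7", "P8", "T7", "T8")
}

default_band_profiles <- function() {
  # relative power per canonical EEG band; rows must differ between classes
  m <- rbind(
    boring = c(delta = 4.0, theta = 3.0, alpha = 1.0, beta = 0.5, gamma = 0.25),
    calm   = c(delta = 1.0, theta = 1.0, alpha = 4.0, beta = 1.0, gamma = 0.25),
    horror = c(delta = 0.5, theta = 0.5, alpha = 1.0, beta = 4.0, gamma = 2.0),
    funny  = c(delta = 2.0, theta = 0.5, alpha = 2.0, beta = 3.0, gamma = 0.5)
  )
  m
}

# two fixed oscillation frequencies (Hz) per canonical band
synthetic_band_freqs <- function() {
  list(delta = c(2, 3), theta = c(5, 7), alpha = c(9, 11),
       beta = c(18, 24), gamma = c(35, 40))
}

#' Specification of a synthetic multi-channel EEG dataset
#'
#' Describes the simulated recording conditions: per subject, class and
#' channel, one long recording is synthesised as a sum of band-limited
#' oscillations whose per-band power follows the class's band profile
#' (random phases, a mild per-recording gain jitter) plus AR(1) noise. The
#' defaults mirror a 14-channel, 128 Hz gaming-emotion recording setup with
#' 4 emotion classes and recordings of 38,252 samples (which frame into 5
#' non-overlapping 7650-sample segments).
#'
#' @param n_subjects Number of subjects (default 4; every subject
#'   contributes one recording per class and channel).
#' @param n_channels Number of channels, up to 14 (default 14).
#' @param rate Sampling rate in Hz (default 128).
#' @param signal_length Samples per recording (default 38252).
#' @param classes Class names (default the four game-emotion categories
#'   boring/calm/horror/funny) or a class count.
#' @param band_profiles Classes x 5 matrix of nonnegative relative band
#'   powers (delta, theta, alpha, beta, gamma); at least two rows must
#'   differ or the generated data carries no class signal.
#' @param noise_sd Innovation standard deviation of the AR(1) noise
#'   (default 1).
#' @param ar_coefficient AR(1) coefficient in (-1, 1) (default 0.9, a
#'   pink-ish spectrum).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_subjects = 4, n_channels = 14, rate = 128,
                           signal_length = 38252,
                           classes = c("boring", "calm", "horror", "funny"),
                           band_profiles = default_band_profiles(),
                           noise_sd = 1, ar_coefficient = 0.9, seed = 42) {
  if (is.numeric(classes) && length(classes) == 1L) {
    classes <- paste0("class", seq_len(classes))
  }
  classes <- as.character(classes)
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L || n_channels > 14L) {
    stop("`n_channels` must be between 1 and 14", call. = FALSE)
  }
  if (!is.matrix(band_profiles) || ncol(band_profiles) != 5L ||
      nrow(band_profiles) < length(classes) || any(band_profiles < 0)) {
    stop("`band_profiles` must be a nonnegative matrix with 5 band columns ",
         "and one row per class", call. = FALSE)
  }
  band_profiles <- band_profiles[seq_along(classes), , drop = FALSE]
  rownames(band_profiles) <- classes
  if (abs(ar_coefficient) >= 1) {
    stop("`ar_coefficient` must lie in (-1, 1)", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_channels = n_channels,
         rate = rate, signal_length = as.integer(signal_length),
         classes = classes, band_profiles = band_profiles,
         noise_sd = noise_sd, ar_coefficient = ar_coefficient,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("Synthetic EEG spec: %d subjects x %d classes x %d channels, %d samples at %g Hz (seed %d)\n",
              x$n_subjects, length(x$classes), x$n_channels,
              x$signal_length, x$rate, x$seed))
  invisible(x)
}

# One synthesised recording: class-profiled sinusoids + AR(1) noise.
# Assumes the RNG state has already been seeded by the caller.
synth_recording <- function(spec, class) {
  n <- spec$signal_length
  tt <- (0:(n - 1)) / spec$rate
  freqs <- synthetic_band_freqs()
  profile <- spec$band_profiles[class, ]
  gain <- stats::runif(1, 0.8, 1.2)
  sig <- numeric(n)
  for (b in seq_along(freqs)) {
    f_b <- freqs[[b]]
    amp <- sqrt(2 * gain * profile[b] / length(f_b))
    for (f in f_b) {
      sig <- sig + amp * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
    }
  }
  if (spec$noise_sd > 0) {
    innov <- stats::rnorm(n, 0, spec$noise_sd)
    sig <- sig + as.numeric(stats::filter(innov, spec$ar_coefficient,
                                          method = "recursive"))
  }
  sig
}

#' Generate the raw (unframed) synthetic recordings
#'
#' Lower-level companion of [generate_dataset()]: returns the full-length
#' recordings so they can be written to disk in a dataset's on-disk layout.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [synthetic_spec()] object.
#' @return A list with one element per subject x class combination, each a
#'   list with `subject`, `class` and `signals` (a `signal_length` x
#'   `n_channels` matrix with channel column names).
#' @export
generate_recordings <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (nrow(unique(spec$band_profiles)) < 2L) {
    warning("all class band profiles are identical; the generated data ",
            "carries no class signal", call. = FALSE)
  }
  set.seed(spec$seed)
  chans <- emotiv_channels()[seq_len(spec$n_channels)]
  out <- list()
  for (subj in seq_len(spec$n_subjects)) {
    for (cl in spec$classes) {
      sig <- vapply(chans, function(ch) synth_recording(spec, cl),
                    numeric(spec$signal_length))
      out[[length(out) + 1L]] <- list(subject = subj, class = cl,
                                      signals = sig)
    }
  }
  out
}

# Assemble framed per-channel collections from a recordings list.
frame_recordings <- function(recordings, channels, frame_length, rate) {
  per_channel <- lapply(channels, function(ch) {
    frames <- list()
    y <- character()
    subject <- integer()
    for (rec in recordings) {
      fr <- segment_frames(rec$signals[, ch], frame_length)
      frames <- c(frames, fr)
      y <- c(y, rep(rec$class, length(fr)))
      subject <- c(subject, rep(rec$subject, length(fr)))
    }
    list(frames = do.call(rbind, frames), y = factor(y), subject = subject)
  })
  names(per_channel) <- channels
  structure(
    list(channels = per_channel, rate = rate, frame_length = frame_length),
    class = "eeg_dataset"
  )
}

#' Generate a framed synthetic EEG dataset
#'
#' Synthesises the recordings described by `spec` and segments each
#' channel's recordings into fixed-length non-overlapping frames, giving
#' per-channel labelled frame collections ready for feature extraction.
#' With the default spec, every channel holds
#' `n_subjects * 4 classes * 5 frames` observations of length 7650.
#'
#' @param spec A [synthetic_spec()] object.
#' @param frame_length Samples per frame (default 7650).
#' @return An object of class `"eeg_dataset"`: list with `channels` (named
#'   list; each entry has `frames` — an observations x `frame_length`
#'   matrix —, `y` and `subject`), `rate` and `frame_length`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(synthetic_spec(n_subjects = 1, n_channels = 2,
#'                                       signal_length = 15300))
#' dim(ds$channels$AF3$frames)   # 8 x 7650 (2 frames x 4 classes)
#' }
#' @export
generate_dataset <- function(spec, frame_length = 7650) {
  recs <- generate_recordings(spec)
  chans <- emotiv_channels()[seq_len(spec$n_channels)]
  frame_recordings(recs, chans, frame_length, spec$rate)
}

#' @export
print.eeg_dataset <- function(x, ...) {
  ch1 <- x$channels[[1]]
  cat(sprintf("EEG dataset: %d channels, %d frames/channel of %d samples at %g Hz\n",
              length(x$channels), nrow(ch1$frames), x$frame_length, x$rate))
  cat("  classes:", paste(sprintf("%s (%d)", levels(ch1$y), table(ch1$y)),
                          collapse = ", "), "\n")
  invisible(x)
}
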