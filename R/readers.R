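# Game code <-> emotion category mapping used in the gaming-emotion CSV
# layout (G1..G4 = boring, calm, horror, funny).
gameemo_games <- function() {
  c(G1 = "boring", G2 = "calm", G3 = "horror", G4 = "funny")
}

fmt_num <- function(x) sprintf("%.17g", x)   # round-trip exact for doubles

#' Write synthetic recordings in the gaming-emotion CSV layout
#'
#' Writes one CSV per subject and game, named `S<subject>G<game>.csv`, with
#' one column per channel — the "all channels in one file" variant accepted
#' by [read_gameemo()]. Values are formatted so that reading them back
#' reproduces the doubles exactly.
#'
#' @param spec A [synthetic_spec()] with exactly 4 classes (the games).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_gameemo <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(spec$classes) != 4L) {
    stop("the gaming-emotion layout has exactly 4 games/classes",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  games <- gameemo_games()
  names(spec$classes) <- names(games)   # class i <-> game code Gi
  recs <- generate_recordings(spec)
  paths <- character()
  for (rec in recs) {
    g <- names(games)[match(rec$class, spec$classes)]
    path <- file.path(dir, sprintf("S%02dG%s.csv", rec$subject,
                                   sub("^G", "", g)))
    df <- as.data.frame(apply(rec$signals, 2, fmt_num))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

# Parse S<subject>G<game>[_<channel>].csv names; returns NULL on mismatch.
parse_gameemo_name <- function(fname) {
  m <- regmatches(fname,
                  regexec("^S(\\d+)G(\\d)(?:_([A-Za-z0-9]+))?\\.csv$", fname))[[1]]
  if (length(m) == 0L) return(NULL)
  list(subject = as.integer(m[2]), game = paste0("G", m[3]),
       channel = if (m[4] == "") NA_character_ else m[4])
}

#' Read a gaming-emotion-style CSV dataset
#'
#' Reads per-subject per-game EEG recordings from `dir` and frames them.
#' Two on-disk layouts are accepted (they may not be mixed):
#' \itemize{
#'   \item `S<subject>G<game>.csv` — one file per recording, one column per
#'     channel (header row of channel names);
#'   \item `S<subject>G<game>_<channel>.csv` — one single-column file per
#'     channel.
#' }
#' Game codes map to class labels G1 = boring, G2 = calm, G3 = horror,
#' G4 = funny.
#'
#' @param dir Directory holding the CSV files.
#' @param frame_length Samples per frame (default 7650).
#' @param channels Channel names expected (default the 14 EMOTIV names
#'   intersected with what the files provide — but every recording must
#'   supply the same set).
#' @return An `"eeg_dataset"` (see [generate_dataset()]), with `subject`
#'   taken from the file names.
#' @export
read_gameemo <- function(dir, frame_length = 7650, channels = NULL) {
  files <- list.files(dir, pattern = "\\.csv$")
  meta <- lapply(files, parse_gameemo_name)
  ok <- !vapply(meta, is.null, TRUE)
  files <- files[ok]
  meta <- meta[ok]
  if (length(files) == 0L) {
    stop("no files matching S<subject>G<game>[_<channel>].csv found in ",
         dir, call. = FALSE)
  }
  games <- gameemo_games()
  per_channel_layout <- !is.na(meta[[1]]$channel)
  recordings <- list()
  if (!per_channel_layout) {
    for (i in seq_along(files)) {
      df <- utils::read.csv(file.path(dir, files[i]), check.names = FALSE)
      chans <- if (is.null(channels)) colnames(df) else channels
      missing <- setdiff(chans, colnames(df))
      if (length(missing) > 0L) {
        stop("file ", files[i], " lacks expected channel column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      bad <- !vapply(df[chans], is.numeric, TRUE)
      if (any(bad)) {
        stop("file ", files[i], " has non-numeric channel column(s): ",
             paste(chans[bad], collapse = ", "), call. = FALSE)
      }
      recordings[[i]] <- list(subject = meta[[i]]$subject,
                              class = games[[meta[[i]]$game]],
                              signals = as.matrix(df[chans]))
    }
    chans <- colnames(recordings[[1]]$signals)
  } else {
    key <- vapply(meta, function(m) sprintf("S%02d%s", m$subject, m$game), "")
    chans <- if (is.null(channels)) {
      sort(unique(vapply(meta, function(m) m$channel, "")))
    } else channels
    for (k in unique(key)) {
      sel <- which(key == k)
      have <- vapply(meta[sel], function(m) m$channel, "")
      missing <- setdiff(chans, have)
      if (length(missing) > 0L) {
        stop("recording ", k, " lacks channel file(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      cols <- lapply(chans, function(ch) {
        f <- files[sel[match(ch, have)]]
        v <- utils::read.csv(file.path(dir, f))[[1]]
        if (!is.numeric(v)) {
          stop("file ", f, " does not contain a numeric signal column",
               call. = FALSE)
        }
        v
      })
      sig <- do.call(cbind, cols)
      colnames(sig) <- chans
      recordings[[length(recordings) + 1L]] <-
        list(subject = meta[[sel[1]]]$subject,
             class = games[[meta[[sel[1]]]$game]],
             signals = sig)
    }
  }
  frame_recordings(recordings, chans, frame_length, rate = 128)
}

#' Write trials in the plain-text DREAMER-style layout
#'
#' Companion writer for [read_dreamer()] (used to build test fixtures and
#' synthetic stand-ins — there is no binary container here; the layout is a
#' plain-text rendering of a DREAMER-like trial structure). Writes
#' `ratings.csv` (columns `trial`, `arousal`, `dominance`, `valence`) and
#' one `trial_<i>.csv` per trial with one column per channel.
#'
#' @param trials List of numeric matrices (samples x channels, channel
#'   column names), one per trial.
#' @param ratings Data frame with columns `arousal`, `dominance`,
#'   `valence`, one row per trial (integer self-ratings, conventionally
#'   1-5).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_dreamer <- function(trials, ratings, dir) {
  stopifnot(is.list(trials), nrow(ratings) == length(trials))
  need <- c("arousal", "dominance", "valence")
  if (!all(need %in% colnames(ratings))) {
    stop("`ratings` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rpath <- file.path(dir, "ratings.csv")
  utils::write.csv(cbind(trial = seq_along(trials), ratings[need]), rpath,
                   row.names = FALSE, quote = FALSE)
  paths <- rpath
  for (i in seq_along(trials)) {
    path <- file.path(dir, sprintf("trial_%02d.csv", i))
    df <- as.data.frame(apply(trials[[i]], 2, fmt_num))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a DREAMER-style trial dataset with low/high labels
#'
#' Reads the plain-text trial layout written by [write_dreamer()]: per-trial
#' per-channel signals plus per-trial self-ratings on the three affective
#' dimensions. The chosen dimension's rating is binarized against
#' `threshold`: `rating >= threshold` labels the trial `"high"`, otherwise
#' `"low"`. The threshold is a required, explicit parameter — there is no
#' canonical cutoff.
#'
#' Trials may have different lengths; they are returned whole (not framed),
#' since every downstream extractor is length-agnostic.
#'
#' @param dir Directory with `ratings.csv` and `trial_<i>.csv` files.
#' @param case One of `"arousal"`, `"dominance"`, `"valence"` (the spelling
#'   `"valance"` is normalized to `"valence"`); case-insensitive.
#' @param threshold Rating cutoff for the low/high split.
#' @return A list of class `"dreamer_trials"`: `signals` (list over trials
#'   of named lists channel -> numeric vector), `labels` (factor
#'   low/high), `ratings` (numeric vector of the chosen case), `case` and
#'   `threshold`.
#' @export
read_dreamer <- function(dir, case, threshold) {
  case <- tolower(as.character(case))
  if (case == "valance") case <- "valence"
  if (!case %in% c("arousal", "dominance", "valence")) {
    stop("unknown `case` \"", case,
         "\"; expected arousal, dominance or valence", call. = FALSE)
  }
  if (missing(threshold) || !is.numeric(threshold)) {
    stop("`threshold` (numeric rating cutoff) is required", call. = FALSE)
  }
  rpath <- file.path(dir, "ratings.csv")
  if (!file.exists(rpath)) {
    stop("no ratings.csv in ", dir, call. = FALSE)
  }
  ratings <- utils::read.csv(rpath)
  if (!case %in% colnames(ratings)) {
    stop("ratings.csv lacks a \"", case, "\" column", call. = FALSE)
  }
  signals <- lapply(ratings$trial, function(i) {
    path <- file.path(dir, sprintf("trial_%02d.csv", i))
    if (!file.exists(path)) {
      stop("missing trial file ", basename(path), call. = FALSE)
    }
    df <- utils::read.csv(path, check.names = FALSE)
    as.list(df)
  })
  r <- ratings[[case]]
  structure(
    list(signals = signals,
         labels = factor(ifelse(r >= threshold, "high", "low"),
                         levels = c("low", "high")),
         ratings = r, case = case, threshold = threshold),
    class = "dreamer_trials"
  )
}

#' @export
print.dreamer_trials <- function(x, ...) {
  cat(sprintf("DREAMER-style trials: %d trials, %d channels, case %s (threshold %g)\n",
              length(x$signals), length(x$signals[[1]]), x$case, x$threshold))
  print(table(x$labels))
  invisible(x)
}
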