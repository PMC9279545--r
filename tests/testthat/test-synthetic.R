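test_that("the default spec frames into the documented layout", {
  spec <- synthetic_spec(n_subjects = 1, n_channels = 3,
                         signal_length = 15300, seed = 5)
  ds <- generate_dataset(spec)
  expect_s3_class(ds, "eeg_dataset")
  expect_named(ds$channels, c("AF3", "AF4", "F3"))
  # 1 subject x 4 classes x floor(15300 / 7650) frames
  expect_identical(dim(ds$channels$AF3$frames), c(8L, 7650L))
  expect_identical(as.integer(table(ds$channels$AF3$y)), rep(2L, 4))
  # default full-length recordings: floor(38252 / 7650) = 5 frames each
  spec2 <- synthetic_spec()
  expect_identical(spec2$signal_length %/% 7650L, 5L)
  expect_identical(spec2$n_channels, 14L)
})

test_that("generation is a pure function of the seed", {
  spec <- synthetic_spec(n_subjects = 1, n_channels = 2,
                         signal_length = 7650, seed = 11)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$channels$AF3$frames, d2$channels$AF3$frames)
  d3 <- generate_dataset(synthetic_spec(n_subjects = 1, n_channels = 2,
                                        signal_length = 7650, seed = 12))
  expect_false(identical(d1$channels$AF3$frames, d3$channels$AF3$frames))
})

test_that("noiseless signals carry the class band-power profile", {
  spec <- synthetic_spec(n_subjects = 1, n_channels = 1,
                         signal_length = 7650, noise_sd = 0, seed = 21)
  recs <- generate_recordings(spec)
  freqs <- list(delta = c(2, 3), theta = c(5, 7), alpha = c(9, 11),
                beta = c(18, 24), gamma = c(35, 40))
  for (rec in recs) {
    x <- rec$signals[, 1]
    n <- length(x)
    spec_dens <- Mod(fft(x))^2 / n^2 * 2      # one-sided power per bin
    fgrid <- (0:(n - 1)) * spec$rate / n
    band_power <- vapply(freqs, function(fb) {
      sum(spec_dens[fgrid >= min(fb) - 1 & fgrid <= max(fb) + 1 &
                      fgrid <= spec$rate / 2])
    }, numeric(1))
    profile <- spec$band_profiles[rec$class, ]
    # compare band-power *ratios* (the per-recording gain cancels)
    expect_equal(unname(band_power / sum(band_power)),
                 unname(profile / sum(profile)), tolerance = 0.05)
  }
})

test_that("distinct class profiles are required to carry signal", {
  prof <- matrix(1, 4, 5)
  expect_warning(
    generate_recordings(synthetic_spec(n_subjects = 1, n_channels = 1,
                                       signal_length = 7650,
                                       band_profiles = prof, seed = 3)),
    "no class signal"
  )
})

test_that("gaming-emotion CSV round trip reproduces the frames exactly", {
  spec <- synthetic_spec(n_subjects = 2, n_channels = 3,
                         signal_length = 15300, seed = 31)
  dir <- file.path(tempdir(), "gameemo_rt")
  unlink(dir, recursive = TRUE)
  write_gameemo(spec, dir)
  expect_length(list.files(dir, pattern = "\\.csv$"), 8)   # 2 subj x 4 games

  ds_disk <- read_gameemo(dir, frame_length = 7650)
  ds_mem <- generate_dataset(spec)
  for (ch in names(ds_mem$channels)) {
    i <- order(ds_mem$channels[[ch]]$subject, ds_mem$channels[[ch]]$y)
    j <- order(ds_disk$channels[[ch]]$subject, ds_disk$channels[[ch]]$y)
    expect_identical(ds_disk$channels[[ch]]$frames[j, ],
                     ds_mem$channels[[ch]]$frames[i, ])
    expect_identical(as.character(ds_disk$channels[[ch]]$y[j]),
                     as.character(ds_mem$channels[[ch]]$y[i]))
  }
})

test_that("the per-channel-file layout and malformed input are handled", {
  dir <- file.path(tempdir(), "gameemo_pc")
  unlink(dir, recursive = TRUE)
  dir.create(dir)
  set.seed(41)
  for (g in 1:4) {
    for (ch in c("AF3", "AF4")) {
      v <- rnorm(7650)
      writeLines(c(ch, sprintf("%.17g", v)),
                 file.path(dir, sprintf("S01G%d_%s.csv", g, ch)))
    }
  }
  ds <- read_gameemo(dir, frame_length = 7650)
  expect_named(ds$channels, c("AF3", "AF4"))
  expect_identical(nrow(ds$channels$AF3$frames), 4L)

  # a missing channel file is reported by name
  file.remove(file.path(dir, "S01G2_AF4.csv"))
  expect_error(read_gameemo(dir, 7650, channels = c("AF3", "AF4")), "AF4")
  expect_error(read_gameemo(tempdir()), "no files matching")
})

test_that("DREAMER-style trials read back with threshold labels", {
  set.seed(61)
  trials <- lapply(c(500, 700), function(n) {
    m <- cbind(AF3 = rnorm(n), AF4 = rnorm(n))
    m
  })
  ratings <- data.frame(arousal = c(2, 4), dominance = c(5, 1),
                        valence = c(3, 3))
  dir <- file.path(tempdir(), "dreamer_rt")
  unlink(dir, recursive = TRUE)
  write_dreamer(trials, ratings, dir)

  d <- read_dreamer(dir, "arousal", threshold = 3)
  expect_length(d$signals, 2)
  expect_named(d$signals[[1]], c("AF3", "AF4"))
  expect_length(d$signals[[2]]$AF3, 700)
  expect_identical(as.character(d$labels), c("low", "high"))
  expect_equal(d$signals[[1]]$AF3, trials[[1]][, "AF3"])

  # boundary: threshold above every rating labels everything low
  d2 <- read_dreamer(dir, "dominance", threshold = 6)
  expect_true(all(d2$labels == "low"))
  # spelling normalization and unknown cases
  d3 <- read_dreamer(dir, "Valance", threshold = 3)
  expect_identical(d3$case, "valence")
  expect_error(read_dreamer(dir, "happiness", threshold = 3), "unknown")
  expect_error(read_dreamer(dir, "arousal"), "threshold")
})
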