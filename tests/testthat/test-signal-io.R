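test_that("montage has 19 unique channels inside the unit disc", {
  m <- montage_1020()
  expect_equal(nrow(m), 19)
  expect_false(any(duplicated(m$channel)))
  expect_true(all(sqrt(m$x^2 + m$y^2) <= 1))
  expect_equal(m$channel, montage_channels())
  # nose at top: frontal electrodes have positive y, occipital negative
  expect_true(all(m$y[m$channel %in% c("Fp1", "Fp2", "Fz")] > 0))
  expect_true(all(m$y[m$channel %in% c("O1", "O2")] < 0))
})

test_that("channel label normalization strips suffixes and fixes case", {
  expect_equal(normalize_channel_labels(c("FP1-REF", "fz", "T3-A1")),
               c("Fp1", "Fz", "T3"))
  expect_error(normalize_channel_labels("XY9"), "channel mismatch")
})

test_that("EDF round-trips shape, labels and samples within quantization", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(19 * 500, sd = 40), 19), 100,
                       montage_channels(), "S7", "patient")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$channels, rec$channels)
  expect_equal(dim(back$data), dim(rec$data))
  expect_equal(back$subject_id, "S7")
  expect_equal(back$group, "patient")
  qstep <- max(abs(rec$data)) / 32767
  expect_lt(max(abs(back$data - rec$data)), 1.5 * qstep)
})

test_that("an EDF missing a montage channel fails with its name", {
  set.seed(2)
  chans <- setdiff(montage_channels(), "Pz")
  rec <- eeg_recording(matrix(rnorm(18 * 200), 18), 100, chans, "S1", "control")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_error(read_edf(path), "Pz")
})

test_that("EDF reference-suffixed labels are normalized and reordered", {
  # channels written in reversed order with -REF suffixes; each channel
  # carries a distinct constant level so the reordering is observable
  chans_raw <- paste0(toupper(rev(montage_channels())), "-REF")
  data <- matrix(rep(seq_len(19) * 10, each = 300), nrow = 19, byrow = TRUE)
  rec <- eeg_recording(data, 100, chans_raw, "S2", "control")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$channels, montage_channels())
  # Fp1 was written last (level 190), O2 first (level 10)
  expect_equal(mean(back$data["Fp1", ]), 190, tolerance = 0.1)
  expect_equal(mean(back$data["O2", ]), 10, tolerance = 0.1)
})

test_that("the epoch container round-trips to float32 precision", {
  set.seed(3)
  es <- epoch_set(array(rnorm(4 * 3 * 50), c(4, 3, 50)), 25,
                  c("F3", "Cz", "O1"), "S9", "patient",
                  band = canonical_bands()$beta)
  path <- withr::local_tempfile(fileext = ".hjep")
  write_epochs(es, path)
  back <- read_epochs(path)
  expect_equal(back$fs, es$fs)
  expect_equal(back$channels, es$channels)
  expect_equal(back$subject_id, es$subject_id)
  expect_equal(back$band$name, "beta")
  expect_equal(back$data, es$data, tolerance = 1e-6)
  expect_error(read_epochs(withr::local_tempfile()), "no such file")
})

test_that("feature CSV has 2 metadata + 285 feature columns and round-trips", {
  tab <- effect_table()
  expect_equal(length(feature_columns(tab)), 285)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  hdr <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_length(hdr, 287)
  expect_equal(hdr[1:2], c("subject_id", "group"))
  back <- read_feature_table(path)
  expect_equal(names(back), names(tab))
  expect_equal(as.matrix(back[, -(1:2)]), as.matrix(tab[, -(1:2)]),
               tolerance = 1e-12)
})

test_that("single band and parameter gives 19 columns in montage order", {
  tab <- subset_features(effect_table(), bands = "beta",
                         parameters = "activity")
  fcols <- feature_columns(tab)
  expect_length(fcols, 19)
  expect_equal(parse_feature_names(fcols)$channel, montage_channels())
})

test_that("duplicated feature names are rejected at write time", {
  tab <- data.frame(subject_id = "a", group = "patient", x = 1, x = 2,
                    check.names = FALSE)
  expect_error(write_feature_table(tab, withr::local_tempfile()),
               "consistency")
  expect_error(write_feature_table(tab[0, ], withr::local_tempfile()),
               "empty")
})

test_that("independent constructions of the same table serialize identically", {
  set.seed(4)
  arr <- array(rnorm(2 * 19 * 64), c(2, 19, 64))
  mk <- function() list(beta = epoch_set(arr, 32, montage_channels(),
                                         "S1", "patient"))
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  write_feature_table(extract_features(mk()), p1)
  write_feature_table(extract_features(mk()), p2)
  expect_identical(readLines(p1), readLines(p2))
})
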