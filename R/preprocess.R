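#' Resample a recording
#'
#' Anti-aliased polyphase resampling (downsampling only). When
#' `target_fs == fs` the recording is returned untouched.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target sampling rate in Hz; must not exceed `rec$fs`
#'   and the ratio must be rational.
#' @return Resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs) {
    stop("unsupported operation: upsampling from ", rec$fs, " to ",
         target_fs, " Hz")
  }
  if (target_fs == rec$fs) return(rec)
  p <- round(target_fs * 1000)
  q <- round(rec$fs * 1000)
  if (abs(p / 1000 - target_fs) > 1e-9 || abs(q / 1000 - rec$fs) > 1e-9) {
    stop("fs ratio must be rational to 1/1000 Hz precision")
  }
  g <- pgcd(p, q)
  p <- p / g
  q <- q / g
  out <- t(apply(rec$data, 1L, function(x) signal::resample(x, p, q)))
  eeg_recording(out, target_fs, rec$channels, rec$subject_id, rec$group)
}

# greatest common divisor (Euclid)
pgcd <- function(a, b) {
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel.
#'
#' @param rec An [eeg_recording()] with at least two channels.
#' @return Re-referenced `eeg_recording`.
#' @export
car_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2) stop("CAR needs at least 2 channels")
  avg <- colMeans(rec$data)
  out <- sweep(rec$data, 2L, avg)
  eeg_recording(out, rec$fs, rec$channels, rec$subject_id, rec$group)
}

#' Band-pass filter a recording
#'
#' Zero-phase FIR filtering of every channel (see [filter_spec()] for the
#' design).
#'
#' @param rec An [eeg_recording()].
#' @param spec A [filter_spec()].
#' @return Filtered `eeg_recording`.
#' @export
bandpass_recording <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  h <- design_fir(spec, rec$fs)
  out <- filter_matrix(rec$data, h)
  eeg_recording(out, rec$fs, rec$channels, rec$subject_id, rec$group)
}

#' Cut a recording into fixed-length epochs
#'
#' Consecutive, non-overlapping windows of exactly `fs * length_s`
#' samples; any trailing remainder is dropped.
#'
#' @param rec An [eeg_recording()].
#' @param length_s Epoch length in seconds (default 4).
#' @param band Optional [band_definition()] tag carried onto the result.
#' @return An [epoch_set()].
#' @export
epoch_recording <- function(rec, length_s = 4, band = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- round(rec$fs * length_s) # samples per epoch
  nep <- ncol(rec$data) %/% spe
  if (nep < 1) {
    stop("signal too short: ", ncol(rec$data) / rec$fs,
         " s recording for ", length_s, " s epochs")
  }
  arr <- array(0, dim = c(nep, nrow(rec$data), spe))
  for (e in seq_len(nep)) {
    arr[e, , ] <- rec$data[, ((e - 1L) * spe + 1L):(e * spe)]
  }
  epoch_set(arr, rec$fs, rec$channels, rec$subject_id, rec$group, band)
}

#' Full preprocessing chain for one recording
#'
#' Fixed stage order: resample to `target_fs`, broadband band-pass, common
#' average reference, per-band zero-phase filtering of the continuous
#' signal, then epoching. Sub-band filtering happens before epoching so
#' filter transients are not re-introduced at every epoch boundary. CAR
#' and the linear filters commute, so their relative order cannot affect
#' the result.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target sampling rate (Hz, default 250).
#' @param broadband Numeric length-2, broadband filter edges in Hz
#'   (default `c(0.5, 45)`).
#' @param epoch_length Epoch length in seconds (default 4).
#' @param bands Named list of [band_definition()]s (default the five
#'   canonical sub-bands).
#' @return List with `broadband` (an [epoch_set()]) and `per_band`
#'   (named list of band-filtered `epoch_set`s).
#' @export
preprocess_recording <- function(rec, target_fs = 250,
                                 broadband = c(0.5, 45),
                                 epoch_length = 4,
                                 bands = canonical_bands()) {
  rec <- resample_recording(rec, target_fs)
  rec <- bandpass_recording(
    rec, filter_spec(broadband[1], broadband[2], kind = "broadband"))
  rec <- car_reference(rec)
  per_band <- lapply(bands, function(b) {
    check_band(b, rec$fs)
    fb <- bandpass_recording(rec, filter_spec(b$low, b$high))
    epoch_recording(fb, epoch_length, band = b)
  })
  list(broadband = epoch_recording(rec, epoch_length), per_band = per_band)
}
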