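#' Configure a synthetic EEG cohort
#'
#' The generator emulates the structure the downstream analysis assumes:
#' per subject and channel, the continuous signal is a sum of independent
#' band-limited Gaussian processes (one per canonical sub-band, each
#' rescaled to unit variance then multiplied by its amplitude scale) plus
#' an optional 1/f "pink" background. Group differences are injected as a
#' multiplicative amplitude factor on chosen (channel, band) cells of the
#' patient group, so Hjorth activity (band variance) differs between
#' groups by the squared factor at those cells.
#'
#' @param n_per_group Subjects per group (default 20 each, i.e. a
#'   40-subject cohort).
#' @param epochs_per_subject Epochs per subject after epoching (default 50).
#' @param epoch_length Epoch length in seconds (default 4).
#' @param fs Sampling rate in Hz (default 250).
#' @param montage Channel labels (default the canonical 19-channel montage).
#' @param band_sd Baseline amplitude scale (signal units, nominally
#'   microvolts) of each band-limited component: a single number applied
#'   to every band, or a numeric vector named by band.
#' @param effect List with elements `factor` (multiplicative amplitude
#'   factor, > 0), `channels`, `bands`: the patient group's amplitude in
#'   those (channel, band) cells is `band_sd * factor`. Default: factor
#'   1.5 on frontal channels F3, F4, Fz, Fp2 in beta and gamma, mirroring
#'   elevated fast-frequency frontal power in patients. Set
#'   `factor = 1` for an exchangeable null cohort.
#' @param pink_background_sd Amplitude (SD) of the 1/f background added to
#'   every channel (default 0.2, i.e. a background whose total variance is
#'   4\% of a unit band component).
#' @param bands Named list of [band_definition()]s used as components
#'   (default the five canonical bands).
#' @param pad_s Seconds of extra signal generated on each side and trimmed
#'   after filtering, keeping filter edge transients out of the epochs
#'   (default 2).
#' @param seed Master seed; per-subject generator seeds are derived from it
#'   (see [generate_cohort()]), so a fixed seed gives byte-identical
#'   cohorts.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = 20, epochs_per_subject = 50,
                              epoch_length = 4, fs = 250,
                              montage = montage_channels(),
                              band_sd = 1,
                              effect = list(factor = 1.5,
                                            channels = c("F3", "F4", "Fz", "Fp2"),
                                            bands = c("beta", "gamma")),
                              pink_background_sd = 0.2,
                              bands = canonical_bands(),
                              pad_s = 2, seed = 1) {
  stopifnot(n_per_group >= 1, epochs_per_subject >= 1, epoch_length > 0,
            fs > 0, pink_background_sd >= 0)
  if (is.null(names(band_sd))) {
    band_sd <- stats::setNames(rep(band_sd[1], length(bands)), names(bands))
  }
  if (any(band_sd < 0)) stop("band_sd must be nonnegative")
  if (!is.null(effect)) {
    stopifnot(effect$factor > 0,
              all(effect$channels %in% montage),
              all(effect$bands %in% names(bands)))
  }
  for (b in bands) check_band(b, fs)
  structure(
    list(n_per_group = n_per_group, epochs_per_subject = epochs_per_subject,
         epoch_length = epoch_length, fs = fs, montage = montage,
         band_sd = band_sd, effect = effect,
         pink_background_sd = pink_background_sd, bands = bands,
         pad_s = pad_s, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Band-limited Gaussian noise
#'
#' White Gaussian noise passed through the package's canonical zero-phase
#' FIR band-pass filter, then rescaled to unit sample variance. Uses the
#' current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param band A [band_definition()].
#' @param n_samples Number of samples; must allow at least 8 cycles of the
#'   band's low edge (`n_samples >= 8 * fs / band$low`).
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length `n_samples` with unit sample variance.
#' @export
band_limited_noise <- function(band, n_samples, fs) {
  check_band(band, fs)
  if (n_samples < 8 * fs / band$low) {
    stop("n_samples too small for stable variance in band ", band$name,
         ": need at least ", ceiling(8 * fs / band$low))
  }
  h <- design_fir(filter_spec(band$low, band$high), fs)
  y <- fir_filtfilt(stats::rnorm(n_samples), h)
  y / sqrt(mean((y - mean(y))^2))
}

# 1/f amplitude-shaped Gaussian noise, unit variance. Spectral amplitude
# ~ f^(-1/2) above 0.5 Hz (flat below, zero at DC).
pink_noise <- function(n_samples, fs) {
  nfft <- stats::nextn(n_samples, 2)
  X <- stats::fft(stats::rnorm(nfft))
  f <- c(0, seq_len(nfft - 1)) * fs / nfft
  f <- pmin(f, fs - f) # two-sided spectrum
  scale <- 1 / sqrt(pmax(f, 0.5))
  scale[1] <- 0
  y <- Re(stats::fft(X * scale, inverse = TRUE) / nfft)[seq_len(n_samples)]
  y / sqrt(mean((y - mean(y))^2))
}

# per-subject generator seed, derived from the master seed; documented
# splitting rule so cohorts are reproducible under subject subsetting
subject_seed <- function(master_seed, subject_index) {
  as.integer((as.numeric(master_seed) * 10007 + subject_index) %% 2147483647)
}

#' Generate a synthetic EEG cohort
#'
#' One [eeg_recording()] per subject, groups balanced. Subject `i` (in
#' generation order: patients first, then controls) is generated from its
#' own seed `(seed * 10007 + i) mod (2^31 - 1)`, so a subset of subjects
#' is reproducible without generating the rest.
#'
#' @param config A [simulation_config()].
#' @return List of `eeg_recording`s, patients (`P01`, `P02`, ...) then
#'   controls (`C01`, ...), each exactly
#'   `epochs_per_subject * epoch_length` seconds long: `pad_s` seconds of
#'   extra signal are generated on each side and trimmed after the
#'   band-limiting filters, so filter edge transients stay out of the
#'   epochs.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ids <- c(sprintf("P%02d", seq_len(config$n_per_group)),
           sprintf("C%02d", seq_len(config$n_per_group)))
  groups <- rep(c("patient", "control"), each = config$n_per_group)
  lapply(seq_along(ids), function(i) {
    set.seed(subject_seed(config$seed, i))
    generate_subject(config, ids[i], groups[i])
  })
}

generate_subject <- function(config, subject_id, group) {
  fs <- config$fs
  n_core <- round(config$epochs_per_subject * config$epoch_length * fs)
  n_pad <- round(config$pad_s * fs)
  n <- n_core + 2L * n_pad
  nch <- length(config$montage)
  data <- matrix(0, nrow = nch, ncol = n)
  for (ci in seq_len(nch)) {
    ch <- config$montage[ci]
    x <- numeric(n)
    for (bn in names(config$bands)) {
      amp <- config$band_sd[[bn]]
      eff <- config$effect
      if (!is.null(eff) && group == "patient" &&
          ch %in% eff$channels && bn %in% eff$bands) {
        amp <- amp * eff$factor
      }
      if (amp > 0) {
        x <- x + amp * band_limited_noise(config$bands[[bn]], n, fs)
      }
    }
    if (config$pink_background_sd > 0) {
      x <- x + config$pink_background_sd * pink_noise(n, fs)
    }
    data[ci, ] <- x
  }
  # drop the generation padding: the epochable core is exact
  core <- (n_pad + 1L):(n_pad + n_core)
  eeg_recording(data[, core, drop = FALSE], fs, config$montage,
                subject_id, group)
}
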