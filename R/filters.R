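#' Specify a band-pass filter
#'
#' Filters are windowed-sinc (Hamming) linear-phase FIR designs applied
#' forward-backward, i.e. zero-phase. The Hamming window gives about 53 dB
#' of stopband attenuation in a single pass; the forward-backward
#' application doubles that in power terms.
#'
#' @param low,high Band edges in Hz.
#' @param kind `"broadband"` or `"subband"`; informational tag only.
#' @param transition_width Transition bandwidth in Hz. Defaults to
#'   `min(2, low / 2)`, which keeps the delta filter's transition narrow
#'   enough not to leak DC while keeping higher-band filters short.
#' @param attenuation Design stopband attenuation in dB (informational;
#'   the Hamming design delivers ~53 dB per pass).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low, high, kind = c("subband", "broadband"),
                        transition_width = NULL, attenuation = 53) {
  kind <- match.arg(kind)
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low) {
    stop("invalid filter band [", low, ", ", high, "]")
  }
  if (is.null(transition_width)) transition_width <- min(2, low / 2)
  structure(list(low = low, high = high, kind = kind,
                 transition_width = transition_width,
                 attenuation = attenuation),
            class = "filter_spec")
}

# Design the FIR band-pass kernel for a spec at sampling rate fs.
# Hamming windowed-sinc; order ~ 3.3 / normalized transition width,
# rounded up to even so the kernel has odd length (type-I linear phase).
design_fir <- function(spec, fs) {
  if (spec$high > fs / 2) {
    stop("invalid filter band: high edge ", spec$high,
         " Hz exceeds Nyquist ", fs / 2, " Hz")
  }
  ntaps <- ceiling(3.3 * fs / spec$transition_width)
  if (ntaps %% 2 == 1) ntaps <- ntaps + 1
  h <- signal::fir1(ntaps, c(spec$low, spec$high) / (fs / 2), type = "pass")
  attr(h, "key") <- sprintf("bp_%g_%g_%g_%d", spec$low, spec$high, fs, ntaps)
  h
}

# cache of FFT'd double-pass kernels, keyed by kernel id + FFT size
.fir_cache <- new.env(parent = emptyenv())

#' Zero-phase FIR filtering of a vector
#'
#' Applies the kernel forward and backward (equivalently: convolves with
#' the kernel's autocorrelation) via FFT convolution, with the group delay
#' removed so the output is sample-aligned with the input. The signal is
#' treated as zero outside its support, so the first and last half-kernel
#' lengths carry edge transients; callers that need transient-free output
#' should pad and trim (the synthetic generator and preprocessing stages
#' do).
#'
#' @param x Numeric vector.
#' @param h FIR kernel as returned by the internal designer.
#' @return Filtered vector, `length(x)`.
#' @keywords internal
fir_filtfilt <- function(x, h) {
  n <- length(x)
  L <- length(h)
  if (L > n) {
    stop("signal too short: ", n, " samples for a ", L, "-tap filter")
  }
  nfft <- stats::nextn(n + 2L * L - 2L, 2)
  key <- paste0(attr(h, "key"), "_", nfft)
  G <- if (!is.null(attr(h, "key")) && !is.null(.fir_cache[[key]])) {
    .fir_cache[[key]]
  } else {
    g <- stats::convolve(h, rev(h), type = "open") # double-pass kernel
    Gf <- stats::fft(c(g, numeric(nfft - length(g))))
    if (!is.null(attr(h, "key"))) .fir_cache[[key]] <- Gf
    Gf
  }
  X <- stats::fft(c(x, numeric(nfft - n)))
  y <- Re(stats::fft(X * G, inverse = TRUE)) / nfft
  # full convolution has length n + 2L - 2; the zero-phase segment starts
  # after the (L-1)-sample group delay of the symmetric double-pass kernel
  y[L:(L + n - 1L)]
}

# Filter every row of a channel x sample matrix with the same kernel.
filter_matrix <- function(mat, h) {
  t(apply(mat, 1L, fir_filtfilt, h = h))
}
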