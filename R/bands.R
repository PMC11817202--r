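#' Define a frequency band
#'
#' A band is a named half-open frequency interval used both by the
#' synthetic generator and by the sub-band filtering stage.
#'
#' @param name Band label (e.g. `"beta"`).
#' @param low Lower edge in Hz; must be positive.
#' @param high Upper edge in Hz; must exceed `low`.
#' @return An object of class `band_definition` with fields `name`, `low`,
#'   `high`.
#' @examples
#' band_definition("beta", 13, 30)
#' @export
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low) {
    stop("invalid band: need 0 < low < high, got [", low, ", ", high, "]")
  }
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' The five canonical EEG sub-bands
#'
#' Delta (0.5-4), theta (4-8), alpha (8-13), beta (13-30) and
#' gamma (30-45) Hz.
#'
#' @param names Optional character vector restricting (and ordering) the
#'   returned bands.
#' @return Named list of [band_definition()] objects.
#' @export
canonical_bands <- function(names = NULL) {
  all <- list(
    delta = band_definition("delta", 0.5, 4),
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 13),
    beta  = band_definition("beta", 13, 30),
    gamma = band_definition("gamma", 30, 45)
  )
  if (is.null(names)) return(all)
  missing <- setdiff(names, names(all))
  if (length(missing)) stop("unknown band(s): ", paste(missing, collapse = ", "))
  all[names]
}

# Validate a band against a sampling rate (Nyquist check).
check_band <- function(band, fs) {
  if (band$high > fs / 2) {
    stop("invalid band: [", band$low, ", ", band$high,
         "] Hz exceeds the Nyquist frequency ", fs / 2, " Hz")
  }
  invisible(band)
}

#' The three Hjorth parameter names in canonical order
#' @return Character vector `c("activity", "mobility", "complexity")`.
#' @export
hjorth_parameters <- function() c("activity", "mobility", "complexity")
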