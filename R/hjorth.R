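#' Hjorth parameters of a signal
#'
#' Activity is the signal's variance with 1/N normalization,
#' `mean((x - mean(x))^2)`; mobility is
#' `sqrt(Var(diff(x)) / Var(x))`, with the derivative realized as the
#' first finite difference (length N-1, no division by the sampling
#' interval, so mobility is in per-sample units); complexity is the
#' mobility of the first difference divided by the mobility of the signal.
#' A pure sinusoid has complexity ~= 1 and mobility
#' `2 sin(pi f / fs)`.
#'
#' Degenerate conventions keep downstream tables free of NaN: a constant
#' signal gives `(0, 0, 0)` (with a warning), and a signal whose first
#' difference is constant (e.g. a linear ramp) gives mobility 0 and
#' complexity 0.
#'
#' @param x Numeric vector, length >= 3.
#' @return Named numeric vector `c(activity, mobility, complexity)`.
#' @examples
#' x <- 2 * sin(2 * pi * 10 * (0:2499) / 250)
#' hjorth(x) # activity ~ 2, mobility ~ 0.2507, complexity ~ 1
#' @export
hjorth <- function(x) {
  if (length(x) < 3) stop("signal too short: Hjorth needs >= 3 samples")
  v0 <- mean((x - mean(x))^2)
  if (v0 == 0) {
    warning("zero-variance signal: Hjorth parameters set to 0")
    return(c(activity = 0, mobility = 0, complexity = 0))
  }
  d1 <- diff(x)
  v1 <- mean((d1 - mean(d1))^2)
  if (v1 == 0) {
    return(c(activity = v0, mobility = 0, complexity = 0))
  }
  d2 <- diff(d1)
  v2 <- mean((d2 - mean(d2))^2)
  mob <- sqrt(v1 / v0)
  c(activity = v0, mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

# Vectorized Hjorth over the rows of an epochs x samples matrix.
# Matches hjorth() exactly (same conventions) but avoids per-epoch loops.
hjorth_rows <- function(X) {
  v0 <- rowMeans((X - rowMeans(X))^2)
  D1 <- X[, -1L, drop = FALSE] - X[, -ncol(X), drop = FALSE]
  v1 <- rowMeans((D1 - rowMeans(D1))^2)
  D2 <- D1[, -1L, drop = FALSE] - D1[, -ncol(D1), drop = FALSE]
  v2 <- rowMeans((D2 - rowMeans(D2))^2)
  mob <- ifelse(v0 > 0 & v1 > 0, sqrt(v1 / v0), 0)
  cpx <- ifelse(v1 > 0 & v2 > 0 & mob > 0, sqrt(v2 / v1) / mob, 0)
  act <- ifelse(v0 > 0, v0, 0)
  cbind(activity = act, mobility = mob, complexity = cpx)
}

#' Feature name for a (band, parameter, channel) cell
#'
#' The canonical naming scheme is `"<band>.<parameter>.<channel>"`, e.g.
#' `"beta.activity.F3"`; canonical column order is band-major,
#' parameter-middle, channel-minor.
#'
#' @param band,parameter,channel Character vectors (recycled).
#' @return Character vector of feature names.
#' @export
feature_name <- function(band, parameter, channel) {
  paste(band, parameter, channel, sep = ".")
}

#' Parse feature names back into their components
#' @param names Character vector of `"<band>.<parameter>.<channel>"` names.
#' @return data.frame with columns `band`, `parameter`, `channel`.
#' @export
parse_feature_names <- function(names) {
  parts <- strsplit(names, ".", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("malformed feature name(s): ", paste(names[bad], collapse = ", "))
  }
  m <- do.call(rbind, parts)
  data.frame(band = m[, 1], parameter = m[, 2], channel = m[, 3],
             stringsAsFactors = FALSE)
}

#' Names of the feature columns of a feature table
#' @param table A feature table (data.frame with `subject_id`, `group`
#'   metadata columns followed by feature columns).
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "group"))
}

#' Extract the Hjorth feature table of one subject
#'
#' One row per epoch; cell `(band, parameter, channel)` holds the Hjorth
#' parameter of that epoch/channel signal filtered to that band. Columns
#' follow the canonical order (band-major, parameter-middle,
#' channel-minor), so the full five-band, 19-channel table has
#' 5 x 3 x 19 = 285 feature columns.
#'
#' @param per_band Named list of band-filtered [epoch_set()]s of one
#'   subject; all must share epoch count, channels and sampling rate.
#' @return A data.frame with columns `subject_id`, `group`, then the
#'   feature columns.
#' @export
extract_features <- function(per_band) {
  stopifnot(is.list(per_band), length(per_band) >= 1,
            !is.null(names(per_band)))
  ref <- per_band[[1]]
  for (es in per_band) {
    if (n_epochs(es) != n_epochs(ref) ||
        !identical(es$channels, ref$channels)) {
      stop("alignment error: epoch sets differ in epoch count or channels")
    }
  }
  params <- hjorth_parameters()
  cols <- list()
  for (bn in names(per_band)) {
    es <- per_band[[bn]]
    # per channel: epochs x 3 matrix of Hjorth parameters
    per_ch <- lapply(seq_along(es$channels),
                     function(ci) hjorth_rows(es$data[, ci, , drop = TRUE]))
    for (p in params) {
      for (ci in seq_along(es$channels)) {
        cols[[feature_name(bn, p, es$channels[ci])]] <- per_ch[[ci]][, p]
      }
    }
  }
  out <- data.frame(subject_id = rep(ref$subject_id, n_epochs(ref)),
                    group = rep(ref$group, n_epochs(ref)),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(cols, optional = TRUE))
}

#' Preprocess a cohort and assemble the pooled feature table
#'
#' Runs [preprocess_recording()] on every recording and stacks the
#' per-subject feature tables of [extract_features()].
#'
#' @param cohort List of [eeg_recording()]s.
#' @param ... Passed to [preprocess_recording()] (`target_fs`,
#'   `broadband`, `epoch_length`, `bands`).
#' @return Pooled feature table (data.frame).
#' @export
cohort_features <- function(cohort, ...) {
  do.call(rbind, lapply(cohort, function(rec) {
    pp <- preprocess_recording(rec, ...)
    extract_features(pp$per_band)
  }))
}
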