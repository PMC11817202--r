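#' Construct an EEG recording
#'
#' The package's in-memory container for a continuous multi-channel
#' recording: a channel-by-sample numeric matrix in microvolts plus the
#' sampling rate, subject identity and group label.
#'
#' @param data Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels (row order of `data`).
#' @param subject_id Subject label.
#' @param group Group label, `"patient"` or `"control"` (or `NA` when
#'   unknown).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels, subject_id = NA_character_,
                          group = NA_character_) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), length(channels) == nrow(data), fs > 0)
  if (anyNA(data) || any(!is.finite(data))) {
    stop("recording contains non-finite values")
  }
  rownames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = as.character(channels),
         subject_id = as.character(subject_id), group = as.character(group)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject=%s group=%s | %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Construct an epoch set
#'
#' Fixed-length epochs of one subject's recording: a 3-way array indexed
#' epoch x channel x sample, together with the sampling rate, epoch length
#' and (optionally) the sub-band the data were filtered to.
#'
#' @param data Numeric array `[epoch, channel, sample]`.
#' @param fs Sampling rate (Hz).
#' @param channels Channel labels matching `dim(data)[2]`.
#' @param subject_id,group Subject metadata carried through the pipeline.
#' @param band Optional [band_definition()] tag.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, channels, subject_id = NA_character_,
                      group = NA_character_, band = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            dim(data)[2] == length(channels))
  if (anyNA(data)) stop("epoch set contains NA")
  structure(
    list(data = data, fs = fs, epoch_length = dim(data)[3] / fs,
         channels = as.character(channels),
         subject_id = as.character(subject_id), group = as.character(group),
         band = band),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> subject=%s group=%s band=%s | %d epochs x %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$group,
              if (is.null(x$band)) "broadband" else x$band$name,
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param x An `epoch_set`.
#' @return Integer epoch count.
#' @export
n_epochs <- function(x) dim(x$data)[1]
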