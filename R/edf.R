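# Minimal EDF (European Data Format) reader/writer for continuous
# multi-channel recordings. EDF stores an ASCII header (256 bytes + 256
# per signal) followed by data records of 16-bit little-endian integers,
# scaled per channel by (physical min/max, digital min/max).

pad_ascii <- function(s, width) {
  r <- charToRaw(as.character(s))
  if (length(r) > width) r <- r[seq_len(width)]
  c(r, rep(charToRaw(" "), width - length(r)))
}

#' Write a recording to an EDF file
#'
#' One-second data records; the sampling rate must therefore be an
#' integer. Per-channel scaling maps the physical range (symmetric around
#' zero, covering the data) onto the full 16-bit digital range, so the
#' round-trip error is bounded by the EDF quantization step.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  spr <- as.integer(fs) # samples per 1-s record
  n_rec <- ncol(rec$data) %/% spr
  if (n_rec < 1) stop("recording shorter than one EDF data record")
  ns <- nrow(rec$data)
  phys_max <- pmax(apply(abs(rec$data[, seq_len(n_rec * spr), drop = FALSE]),
                         1, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    pad_ascii("0", 8),
    pad_ascii(paste(rec$subject_id, rec$group), 80),
    pad_ascii("hjortheeg export", 80),
    pad_ascii("01.01.00", 8),
    pad_ascii("00.00.00", 8),
    pad_ascii(256 * (ns + 1), 8),
    pad_ascii("", 44),
    pad_ascii(n_rec, 8),
    pad_ascii(1, 8),
    pad_ascii(ns, 4)
  )
  field <- function(vals, width) {
    do.call(c, lapply(vals, pad_ascii, width = width))
  }
  hdr <- c(hdr,
           field(rec$channels, 16),
           field(rep("", ns), 80),
           field(rep("uV", ns), 8),
           field(sprintf("%.8g", -phys_max), 8),
           field(sprintf("%.8g", phys_max), 8),
           field(rep(-32768L, ns), 8),
           field(rep(32767L, ns), 8),
           field(rep("", ns), 80),
           field(rep(spr, ns), 8),
           field(rep("", ns), 32))
  writeBin(hdr, con)
  scale <- 32767 / phys_max
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round(rec$data[ch, idx] * scale[ch]))
      writeBin(pmax(pmin(dig, 32767L), -32768L), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file as a recording
#'
#' Channel labels are normalized to the canonical montage names
#' (case-insensitive; trailing reference suffixes such as `-REF` are
#' stripped) and channels are reordered to canonical montage order. A
#' file that does not carry exactly the 19 montage channels raises a
#' channel-mismatch error naming the offending or missing labels.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()] in microvolts.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  ver <- rd(8)
  patient <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("unparseable EDF header")
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fld(16)
  fld(80)
  fld(8)
  pmin_ <- as.numeric(fld(8))
  pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8))
  dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1) {
    stop("EDF with per-channel sampling rates is not supported")
  }
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  offset <- pmin_ - gain * dmin
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      data[ch, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        raw * gain[ch] + offset[ch]
    }
  }
  perm <- match_montage(labels)
  meta <- strsplit(patient, " +")[[1]]
  eeg_recording(data[perm, , drop = FALSE], fs, montage_channels(),
                subject_id = if (length(meta) >= 1) meta[1] else NA_character_,
                group = if (length(meta) >= 2) meta[2] else NA_character_)
}
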