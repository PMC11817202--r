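# Single-file binary epoch container. Layout (little-endian):
#   magic "HJEP0001" (8 bytes)
#   fs, epoch_length                      : 2 x float64
#   n_epochs, n_channels, n_samples       : 3 x int32
#   subject_id, group, band tag           : length-prefixed UTF-8 strings
#     (band tag: "" for broadband, else "name low high")
#   channel labels                        : n_channels length-prefixed strings
#   data                                  : float32, epoch-major, then
#                                           channel, then sample
# Values are stored as 32-bit floats: a cacheable working format, not an
# archival one.

write_str <- function(con, s) {
  r <- charToRaw(enc2utf8(as.character(s)))
  writeBin(length(r), con, size = 4, endian = "little")
  writeBin(r, con)
}

read_str <- function(con) {
  n <- readBin(con, "integer", size = 4, endian = "little")
  rawToChar(readBin(con, "raw", n))
}

#' Write an epoch set to the package's binary epoch container
#'
#' @param es An [epoch_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_epochs()]
#' @export
write_epochs <- function(es, path) {
  stopifnot(inherits(es, "epoch_set"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("HJEP0001"), con)
  writeBin(c(es$fs, es$epoch_length), con, size = 8, endian = "little")
  writeBin(as.integer(dim(es$data)), con, size = 4, endian = "little")
  write_str(con, es$subject_id)
  write_str(con, es$group)
  band_tag <- if (is.null(es$band)) "" else {
    paste(es$band$name, es$band$low, es$band$high)
  }
  write_str(con, band_tag)
  for (ch in es$channels) write_str(con, ch)
  writeBin(as.numeric(aperm(es$data, c(3, 2, 1))), con, size = 4,
           endian = "little")
  invisible(path)
}

#' Read an epoch set from the binary epoch container
#' @param path File written by [write_epochs()].
#' @return An [epoch_set()].
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (magic != "HJEP0001") stop("not an epoch container: ", path)
  hdr <- readBin(con, "numeric", 2, size = 8, endian = "little")
  dims <- readBin(con, "integer", 3, size = 4, endian = "little")
  subject_id <- read_str(con)
  group <- read_str(con)
  band_tag <- read_str(con)
  band <- if (nzchar(band_tag)) {
    p <- strsplit(band_tag, " ")[[1]]
    band_definition(p[1], as.numeric(p[2]), as.numeric(p[3]))
  }
  channels <- vapply(seq_len(dims[2]), function(i) read_str(con),
                     character(1))
  vals <- readBin(con, "numeric", prod(dims), size = 4, endian = "little")
  data <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  epoch_set(data, hdr[1], channels, subject_id, group, band)
}

#' Write a feature table to CSV
#'
#' Header row, one row per epoch; columns `subject_id`, `group`, then the
#' feature columns in their canonical order, full numeric precision.
#'
#' @param table Feature table (data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (nrow(table) == 0) stop("empty feature table")
  if (anyDuplicated(names(table))) {
    stop("internal consistency error: duplicated feature names ",
         paste(unique(names(table)[duplicated(names(table))]), collapse = ", "))
  }
  utils::write.csv(format(table, digits = 17, scientific = NA, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return Feature table data.frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
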