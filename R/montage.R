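#' The canonical 19-channel 10-20 montage
#'
#' Channel order is fixed and treated as canonical throughout the package:
#' Fp1, Fp2, F7, F3, Fz, F4, F8, T3, C3, Cz, C4, T4, T5, P3, Pz, P4, T6,
#' O1, O2. Two-dimensional scalp positions are an azimuthal-equidistant
#' (polar) projection of the standard 10-20 spherical placements: radius is
#' proportional to the polar angle from the vertex (Cz), the nose points to
#' +y and the right ear to +x, with the outer electrode ring at radius 0.8
#' inside the unit disc.
#'
#' @return A data.frame with columns `channel`, `x`, `y` (one row per
#'   channel, canonical order).
#' @export
montage_1020 <- function() {
  # polar angle from vertex (deg), azimuth from nose, +ve toward right ear
  tab <- matrix(c(
    72, -18,   # Fp1
    72,  18,   # Fp2
    72, -54,   # F7
    51, -34,   # F3
    36,   0,   # Fz
    51,  34,   # F4
    72,  54,   # F8
    72, -90,   # T3
    36, -90,   # C3
     0,   0,   # Cz
    36,  90,   # C4
    72,  90,   # T4
    72, -126,  # T5
    51, -146,  # P3
    36, 180,   # Pz
    51, 146,   # P4
    72, 126,   # T6
    72, -162,  # O1
    72, 162    # O2
  ), ncol = 2, byrow = TRUE)
  r <- tab[, 1] / 90 # outer ring (polar 72 deg) maps to radius 0.8
  az <- tab[, 2] * pi / 180
  data.frame(
    channel = montage_channels(),
    x = r * sin(az),
    y = r * cos(az),
    stringsAsFactors = FALSE
  )
}

#' Canonical channel labels of the 19-channel montage
#' @return Character vector of 19 labels in canonical order.
#' @export
montage_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Normalize raw channel labels to montage names
#'
#' Matching is case-insensitive and strips trailing reference suffixes
#' such as `-REF`, `-LE`, `-A1`, `-A2`, `-AVG` and `-M1`/`-M2`, so labels
#' like `"FP1-REF"` map to `"Fp1"`.
#'
#' @param labels Character vector of raw labels.
#' @return Character vector of canonical labels (same length/order).
#'   Unmatched labels raise a channel-mismatch error naming the offenders.
#' @export
normalize_channel_labels <- function(labels) {
  stripped <- sub("[-_ ](REF|LE|AVG|AV|A1|A2|M1|M2)$", "",
                  toupper(trimws(labels)))
  stripped <- sub("^EEG[ _-]?", "", stripped)
  canon <- montage_channels()
  idx <- match(stripped, toupper(canon))
  if (anyNA(idx)) {
    stop("channel mismatch: unrecognized label(s) ",
         paste(labels[is.na(idx)], collapse = ", "))
  }
  canon[idx]
}

# Assert that labels cover the full montage exactly once; returns the
# permutation putting them in canonical order.
match_montage <- function(labels) {
  canon <- montage_channels()
  norm <- normalize_channel_labels(labels)
  if (anyDuplicated(norm)) {
    stop("channel mismatch: duplicated channel(s) ",
         paste(unique(norm[duplicated(norm)]), collapse = ", "))
  }
  missing <- setdiff(canon, norm)
  if (length(missing)) {
    stop("channel mismatch: missing channel(s) ",
         paste(missing, collapse = ", "))
  }
  match(canon, norm)
}
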