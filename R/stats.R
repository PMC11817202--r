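#' Channel-wise Wilcoxon rank-sum statistics
#'
#' For one (band, parameter) pair, compares patients against controls at
#' every channel with the two-sample Wilcoxon rank-sum test. The z-value
#' comes from the tie-corrected normal approximation of the Mann-Whitney
#' U statistic (no continuity correction), signed so that positive z
#' means patient values are stochastically larger. The two-sided p-value
#' is exact (from the null distribution of U) when there are no ties and
#' both groups have at most 25 observations, and otherwise uses the
#' normal approximation.
#'
#' The default analysis unit is the per-subject mean of the feature,
#' which avoids pseudo-replication across a subject's correlated epochs;
#' `unit = "epoch"` tests all epochs individually. Raw p-values are
#' reported; `p_adjust = "BH"` optionally applies Benjamini-Hochberg
#' correction across channels.
#'
#' @param table Feature table with `subject_id` and `group` columns.
#' @param parameter Hjorth parameter name (e.g. `"activity"`).
#' @param band Band label (e.g. `"beta"`).
#' @param unit `"subject_mean"` (default) or `"epoch"`.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param positive Group treated as the "larger is positive z" direction
#'   (default `"patient"`).
#' @return data.frame with one row per channel: `channel`, `z`, `p`,
#'   `significant`, plus group sizes.
#' @export
wilcoxon_map <- function(table, parameter, band,
                         unit = c("subject_mean", "epoch"), alpha = 0.05,
                         p_adjust = c("none", "BH"), positive = "patient") {
  unit <- match.arg(unit)
  p_adjust <- match.arg(p_adjust)
  stopifnot(all(c("subject_id", "group") %in% names(table)))
  groups <- unique(table$group)
  if (length(groups) != 2 || !(positive %in% groups)) {
    stop("configuration error: need both groups present, with '",
         positive, "' among them")
  }
  info <- parse_feature_names(feature_columns(table))
  use <- which(info$band == band & info$parameter == parameter)
  if (!length(use)) stop("no features for band=", band, " parameter=", parameter)
  rows <- lapply(use, function(j) {
    col <- feature_columns(table)[j]
    if (unit == "subject_mean") {
      agg <- tapply(table[[col]], table$subject_id, mean)
      grp <- tapply(table$group, table$subject_id, `[`, 1)
      x <- agg[grp == positive]
      z <- agg[grp != positive]
    } else {
      x <- table[[col]][table$group == positive]
      z <- table[[col]][table$group != positive]
    }
    rs <- rank_sum_test(as.numeric(x), as.numeric(z))
    data.frame(channel = info$channel[j], n_patient = length(x),
               n_control = length(z), z = rs$z, p = rs$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  attr(out, "band") <- band
  attr(out, "parameter") <- parameter
  attr(out, "unit") <- unit
  out
}

# Two-sample rank-sum: z from the tie-corrected normal approximation,
# p exact (stats::pwilcox) when tie-free and small, else normal.
rank_sum_test <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  all_v <- c(x, y)
  r <- rank(all_v)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 # Mann-Whitney U of x
  mu <- n1 * n2 / 2
  ties <- table(all_v)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (u1 - mu) / sqrt(sigma2) else 0
  p <- if (!any(ties > 1) && max(n1, n2) <= 25) {
    lo <- stats::pwilcox(u1, n1, n2)
    hi <- stats::pwilcox(u1 - 1, n1, n2, lower.tail = FALSE)
    min(1, 2 * min(lo, hi))
  } else {
    2 * stats::pnorm(-abs(z))
  }
  list(z = z, p = p, u = u1)
}
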