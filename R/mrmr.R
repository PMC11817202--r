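#' Configure mRMR feature selection
#'
#' @param k Number of features to select (default 12).
#' @param scheme `"MIQ"` (relevance / mean redundancy, the common toolbox
#'   default) or `"MID"` (relevance - mean redundancy).
#' @param n_bins Equal-frequency discretization bins for the mutual
#'   information estimator (default 5).
#' @param class_prior `"empirical"` (label marginal weighted by observed
#'   class frequencies; the default) or `"uniform"` (classes weighted
#'   equally in the label marginal). With balanced classes the two
#'   coincide.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(k = 12, scheme = c("MIQ", "MID"), n_bins = 5,
                             class_prior = c("empirical", "uniform")) {
  scheme <- match.arg(scheme)
  class_prior <- match.arg(class_prior)
  stopifnot(k >= 1, n_bins >= 2)
  structure(list(k = as.integer(k), scheme = scheme,
                 n_bins = as.integer(n_bins), class_prior = class_prior),
            class = "selection_config")
}

#' Equal-frequency discretization
#'
#' Values are ranked (ties share the rank of their first occurrence, so
#' tied values always land in the same, lower bin) and split into
#' `n_bins` bins of as-equal-as-possible occupancy. A constant column
#' collapses to a single code.
#'
#' @param values Finite numeric vector.
#' @param n_bins Number of bins.
#' @return Integer codes in `0:(n_bins - 1)`.
#' @export
discretize <- function(values, n_bins) {
  stopifnot(all(is.finite(values)), n_bins >= 2)
  n <- length(values)
  r <- rank(values, ties.method = "min")
  codes <- as.integer(floor((r - 1) * n_bins / n))
  # ties.method = "min" can only pull values into lower bins, never split
  # a tie group across bins upward; re-map to dense codes for constants
  codes
}

#' Plug-in mutual information of two discrete code vectors
#'
#' `sum p(a,b) log(p(a,b) / (p(a) p(b)))` over observed cells, in nats.
#' Optional per-observation weights reweight the joint (used for the
#' `class_prior` setting).
#'
#' @param a,b Integer code vectors of equal length.
#' @param w Optional nonnegative observation weights (default uniform).
#' @return Mutual information in nats (>= 0, symmetric).
#' @export
mutual_information <- function(a, b, w = NULL) {
  if (length(a) != length(b)) {
    stop("alignment error: code vectors of length ", length(a), " and ",
         length(b))
  }
  if (is.null(w)) {
    joint <- table(a, b)
    p <- joint / sum(joint)
  } else {
    stopifnot(length(w) == length(a), all(w >= 0))
    p <- tapply(w, list(a, b), sum, default = 0)
    p <- p / sum(p)
  }
  pa <- rowSums(p)
  pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

#' Greedy mRMR feature selection
#'
#' The first pick maximizes relevance (mutual information with the class
#' label); each subsequent pick maximizes relevance / mean-redundancy
#' (MIQ, redundancy floored at 1e-12) or relevance - mean-redundancy
#' (MID) against the already-selected set. Ties are broken by canonical
#' column order. All mutual information is estimated on equal-frequency
#' discretized columns. With `class_prior = "empirical"` the label
#' marginal uses observed class frequencies; `"uniform"` reweights
#' observations so every class carries equal total weight.
#'
#' @param table Feature table (data.frame with `subject_id`, `group`
#'   metadata), or a plain numeric data.frame/matrix of features.
#' @param labels Class vector (defaults to `table$group` when present).
#' @param config A [selection_config()].
#' @return An object of class `selection_result`: list with `ordered`
#'   (selected names in pick order), `relevance` (MI with the label, nats,
#'   for every candidate), `redundancy_at_pick` and `score_at_pick`
#'   (per selected feature).
#' @export
mrmr <- function(table, labels = NULL, config = selection_config()) {
  if (is.null(labels) && !is.null(table$group)) labels <- table$group
  stopifnot(!is.null(labels))
  fcols <- feature_columns(as.data.frame(table))
  X <- as.data.frame(table)[fcols]
  if (length(unique(labels)) < 2) stop("need >= 2 classes for selection")
  if (config$k > length(fcols)) {
    stop("configuration error: k = ", config$k, " exceeds the ",
         length(fcols), " available features")
  }
  codes <- lapply(X, discretize, n_bins = config$n_bins)
  y <- as.integer(factor(labels))
  w <- if (config$class_prior == "uniform") {
    tab <- table(y)
    (1 / tab[as.character(y)]) * length(y) / length(tab)
  } else NULL
  relevance <- vapply(codes, mutual_information, numeric(1), b = y, w = w)
  eps <- 1e-12
  selected <- integer(0)
  red_at_pick <- numeric(0)
  score_at_pick <- numeric(0)
  # pairwise feature MI computed lazily and cached
  pair_mi <- matrix(NA_real_, length(fcols), length(fcols))
  for (pick in seq_len(config$k)) {
    cand <- setdiff(seq_along(fcols), selected)
    red <- if (length(selected) == 0) rep(0, length(cand)) else {
      vapply(cand, function(j) {
        mean(vapply(selected, function(s) {
          if (is.na(pair_mi[j, s])) {
            pair_mi[j, s] <<- pair_mi[s, j] <<-
              mutual_information(codes[[j]], codes[[s]])
          }
          pair_mi[j, s]
        }, numeric(1)))
      }, numeric(1))
    }
    score <- if (config$scheme == "MIQ") {
      relevance[cand] / pmax(red, eps)
    } else {
      relevance[cand] - red
    }
    best <- cand[which.max(score)] # which.max takes the first = lowest
    selected <- c(selected, best)  # canonical column index on ties
    red_at_pick <- c(red_at_pick, red[match(best, cand)])
    score_at_pick <- c(score_at_pick, max(score))
  }
  structure(
    list(ordered = fcols[selected],
         relevance = relevance,
         redundancy_at_pick = stats::setNames(red_at_pick, fcols[selected]),
         score_at_pick = stats::setNames(score_at_pick, fcols[selected]),
         config = config),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s, k=%d\n", x$config$scheme,
              length(x$ordered)))
  for (i in seq_along(x$ordered)) {
    f <- x$ordered[i]
    cat(sprintf("  %2d. %-28s relevance=%.4f redundancy=%.4f\n", i, f,
                x$relevance[[f]], x$redundancy_at_pick[[f]]))
  }
  invisible(x)
}
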