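#' Configure LIME explanations
#'
#' @param n_samples Perturbations drawn around each explained instance
#'   (default 1000, minimum 100).
#' @param kernel_width Proximity kernel scale on standardized distances;
#'   default `0.75 * sqrt(d)` with `d` the feature count (the widely used
#'   tabular-LIME default).
#' @param top_k Number of surrogate features retained (default: all
#'   features of the instance).
#' @param ridge Ridge penalty of the weighted surrogate fit (default
#'   1e-3; any small positive value only stabilizes the solve).
#' @param seed Seed for the perturbation draw.
#' @return An object of class `lime_config`.
#' @export
lime_config <- function(n_samples = 1000, kernel_width = NULL,
                        top_k = NULL, ridge = 1e-3, seed = 1) {
  stopifnot(n_samples >= 100, is.null(kernel_width) || kernel_width > 0)
  structure(list(n_samples = as.integer(n_samples),
                 kernel_width = kernel_width, top_k = top_k,
                 ridge = ridge, seed = as.integer(seed)),
            class = "lime_config")
}

#' Explain one prediction with a local linear surrogate
#'
#' Draws `n_samples` Gaussian perturbations centred on the instance with
#' per-feature SDs taken from the training distribution, weights each by
#' `exp(-D^2 / kernel_width^2)` where `D` is the standardized Euclidean
#' distance to the instance, keeps the `top_k` features with the largest
#' absolute weighted univariate association with the model output, and
#' fits a weighted ridge regression of the model's continuous decision
#' scores on the standardized perturbed features. The signed surrogate
#' coefficients are the explanation; for a linear model with all features
#' retained they are proportional to the model's own coefficients.
#'
#' @param predict_fn Function taking an `n x d` feature matrix (original
#'   units, columns named like the instance) and returning a numeric
#'   decision score per row.
#' @param instance Named numeric feature vector to explain.
#' @param train_stats List with numeric vectors `mean` and `sd` per
#'   feature (training-fold statistics); all perturbed features need
#'   `sd > 0`.
#' @param cfg A [lime_config()].
#' @return An object of class `lime_explanation`: list with `weights`
#'   (named, length `top_k`), `r2` (weighted R^2 of the surrogate),
#'   `intercept` and `degenerate` (TRUE when the model output was
#'   constant over the perturbations, in which case all weights are 0).
#' @export
lime_explain <- function(predict_fn, instance, train_stats,
                         cfg = lime_config()) {
  d <- length(instance)
  sdv <- rep_len(train_stats$sd, d)
  mu <- rep_len(train_stats$mean, d)
  if (any(sdv <= 0)) stop("train_stats$sd must be positive for all features")
  kw <- if (is.null(cfg$kernel_width)) 0.75 * sqrt(d) else cfg$kernel_width
  top_k <- min(if (is.null(cfg$top_k)) d else cfg$top_k, d)
  set.seed(cfg$seed)
  E <- matrix(stats::rnorm(cfg$n_samples * d), cfg$n_samples, d) # std normal
  Z <- sweep(E, 2L, sdv, `*`)
  Z <- sweep(Z, 2L, as.numeric(instance), `+`)
  colnames(Z) <- names(instance)
  D2 <- rowSums(E^2) # standardized squared distance to the instance
  w <- exp(-D2 / kw^2)
  y <- as.numeric(predict_fn(Z))
  stopifnot(length(y) == cfg$n_samples)
  S <- sweep(sweep(Z, 2L, mu), 2L, sdv, `/`) # standardized features
  ybar <- sum(w * y) / sum(w)
  if (stats::sd(y) == 0) {
    warning("constant model output over perturbations: zero explanation")
    wts <- stats::setNames(rep(0, top_k), names(instance)[seq_len(top_k)])
    return(structure(list(weights = wts, r2 = 0, intercept = ybar,
                          degenerate = TRUE), class = "lime_explanation"))
  }
  # feature sub-selection: largest absolute weighted covariance with y
  sbar <- colSums(w * S) / sum(w)
  assoc <- abs(colSums(w * sweep(S, 2L, sbar) * (y - ybar)) / sum(w))
  keep <- order(assoc, decreasing = TRUE)[seq_len(top_k)]
  X <- cbind(1, S[, keep, drop = FALSE])
  XtW <- t(X * w)
  A <- XtW %*% X
  diag(A)[-1] <- diag(A)[-1] + cfg$ridge # intercept unpenalized
  beta <- drop(solve(A, XtW %*% y))
  fit <- drop(X %*% beta)
  r2 <- 1 - sum(w * (y - fit)^2) / sum(w * (y - ybar)^2)
  structure(
    list(weights = stats::setNames(beta[-1], colnames(Z)[keep]),
         r2 = r2, intercept = beta[1], degenerate = FALSE),
    class = "lime_explanation"
  )
}

#' @export
print.lime_explanation <- function(x, ...) {
  cat(sprintf("<lime_explanation> %d features, surrogate R^2 = %.3f%s\n",
              length(x$weights), x$r2,
              if (x$degenerate) " (degenerate)" else ""))
  w <- sort(abs(x$weights), decreasing = TRUE)
  for (f in names(w)) cat(sprintf("  %-28s %+0.4f\n", f, x$weights[[f]]))
  invisible(x)
}

#' Aggregate explanations into a per-channel importance map
#'
#' A channel's importance is the mean absolute surrogate weight over all
#' explanations and over that channel's features in the given band; the
#' map is rescaled so its maximum is 1. Channels of the montage that
#' never received a selected feature score 0.
#'
#' @param explanations List of [lime_explain()] results.
#' @param band Band label to aggregate (e.g. `"beta"`).
#' @param channels Channel set of the map (default the canonical montage).
#' @return An object of class `explanation_map`: data.frame with columns
#'   `channel`, `importance`, and attributes `band`.
#' @export
aggregate_channel_importance <- function(explanations, band,
                                         channels = montage_channels()) {
  stopifnot(length(explanations) >= 1)
  vals <- stats::setNames(lapply(channels, function(ch) numeric(0)), channels)
  for (ex in explanations) {
    info <- parse_feature_names(names(ex$weights))
    sel <- info$band == band & info$channel %in% channels
    for (i in which(sel)) {
      ch <- info$channel[i]
      vals[[ch]] <- c(vals[[ch]], abs(ex$weights[[i]]))
    }
  }
  imp <- vapply(vals, function(v) if (length(v)) mean(v) else 0, numeric(1))
  if (max(imp) > 0) imp <- imp / max(imp)
  structure(data.frame(channel = channels, importance = unname(imp),
                       stringsAsFactors = FALSE),
            band = band, class = c("explanation_map", "data.frame"))
}

#' Export a channel map with scalp positions
#'
#' Joins per-channel scores to the montage's 2-D positions and writes a
#' CSV ready for topographic rendering.
#'
#' @param map An `explanation_map` or any data.frame with `channel` plus
#'   score columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_channel_map <- function(map, path) {
  out <- merge(montage_1020(), as.data.frame(map), by = "channel",
               sort = FALSE)
  out <- out[match(montage_channels(), out$channel), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Explain every held-out epoch of a cross-validated evaluation
#'
#' Runs [lime_explain()] against each fold's fitted model (the report
#' must have been produced with `run_loso(..., keep_models = TRUE)`),
#' explaining the fold's held-out epochs in the original feature units;
#' training-fold means/SDs supply the perturbation scales. Each instance
#' gets its own deterministic seed derived from `cfg$seed`.
#'
#' @param table The feature table the report was computed from.
#' @param report An `evaluation_report` with kept models.
#' @param cfg A [lime_config()].
#' @param max_per_fold Explain at most this many held-out epochs per fold
#'   (default all).
#' @return List of `lime_explanation` objects, named
#'   `"<subject>:<epoch row>"`.
#' @export
explain_evaluation <- function(table, report, cfg = lime_config(),
                               max_per_fold = Inf) {
  if (is.null(report$folds[[1]]$model)) {
    stop("report carries no fold models; rerun run_loso with keep_models = TRUE")
  }
  standardize <- needs_standardization(report$classifier)
  counter <- 0L
  out <- list()
  for (f in report$folds) {
    mu <- f$train_mean
    sdv <- f$train_sd
    model <- f$model
    predict_fn <- function(X) {
      Xs <- if (standardize) scale(X, mu, sdv) else X
      predict_model(model, Xs)$score
    }
    rows <- f$test_rows[seq_len(min(length(f$test_rows), max_per_fold))]
    for (r in rows) {
      counter <- counter + 1L
      inst <- as.numeric(table[r, f$features])
      names(inst) <- f$features
      icfg <- cfg
      icfg$seed <- cfg$seed + counter
      out[[paste0(f$held_out_subject, ":", r)]] <-
        lime_explain(predict_fn, inst, list(mean = mu, sd = sdv), icfg)
    }
  }
  out
}
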