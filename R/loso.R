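#' Leave-one-subject-out folds
#'
#' One fold per distinct subject: the test set is exactly that subject's
#' rows, the training set everything else. Test sets partition the rows.
#'
#' @param subject_ids Per-row subject labels.
#' @return List of folds, each `list(subject, train, test)` with integer
#'   row indices.
#' @export
loso_folds <- function(subject_ids) {
  subjects <- unique(subject_ids)
  if (length(subjects) < 2) {
    stop("configuration error: leave-one-subject-out needs >= 2 subjects")
  }
  lapply(subjects, function(s) {
    test <- which(subject_ids == s)
    list(subject = s, train = setdiff(seq_along(subject_ids), test),
         test = test)
  })
}

#' Exact one-sided binomial test against chance
#'
#' Upper tail probability `P(X >= n_correct)` for
#' `X ~ Binomial(n_epochs, chance)`: the probability of doing at least
#' this well by guessing. A subject with all 50 of 50 epochs correct at
#' chance 0.5 has p = 0.5^50 ~= 8.88e-16.
#'
#' @param n_correct Correctly classified epochs.
#' @param n_epochs Total epochs.
#' @param chance Success probability under the null (default 0.5).
#' @return One-sided p-value in (0, 1].
#' @export
binomial_subject_test <- function(n_correct, n_epochs, chance = 0.5) {
  if (chance <= 0 || chance >= 1) {
    stop("configuration error: chance must lie in (0, 1)")
  }
  stopifnot(n_correct >= 0, n_correct <= n_epochs)
  stats::pbinom(n_correct - 1, n_epochs, chance, lower.tail = FALSE)
}

#' ROC curve and AUC from pooled decision scores
#'
#' The ROC is traced by sweeping a threshold over all distinct scores
#' (tied scores move the operating point jointly); the AUC equals the
#' normalized Mann-Whitney statistic `U / (n_pos * n_neg)` with tied
#' scores contributing 1/2, i.e. the probability that a random positive
#' outranks a random negative.
#'
#' @param scores Numeric decision scores, higher = more positive.
#' @param labels Class labels.
#' @param positive The positive class (default `"patient"`).
#' @return List with `roc` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "patient") {
  pos <- labels == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("undefined metric: ROC needs both classes present")
  }
  r <- rank(scores) # ties averaged
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord])
  fp <- cumsum(!pos[ord])
  last <- rev(!duplicated(rev(scores[ord]))) # last index of each tie block
  roc <- data.frame(threshold = c(Inf, scores[ord][last]),
                    fpr = c(0, fp[last] / n_neg),
                    tpr = c(0, tp[last] / n_pos))
  list(roc = roc, auc = auc)
}

#' Leave-one-subject-out evaluation of a feature table
#'
#' For every fold, feature standardization (train mean/SD; applied for
#' SVM, LDA and KNN) and mRMR selection are fitted on the training rows
#' only (`mode = "per_fold"`, the default), the classifier is trained on
#' the selected standardized training rows, and the held-out subject's
#' epochs are predicted. `mode = "global"` instead runs mRMR once on the
#' full table before cross-validation; it reproduces a common but
#' leakage-prone protocol and is provided for comparison only. Metrics
#' are pooled over all held-out epochs with the patient class positive;
#' subject-level majority-vote accuracy and per-subject exact binomial
#' tests against chance are reported alongside.
#'
#' @param table Feature table with `subject_id` and `group` columns.
#' @param clf A [classifier_spec()].
#' @param sel A [selection_config()]; `NULL` skips selection and uses all
#'   feature columns.
#' @param mode `"per_fold"` or `"global"` (see above).
#' @param positive Positive class label (default `"patient"`).
#' @param keep_models Keep each fold's fitted model and training
#'   statistics on the report (needed for LIME explanation of the fold
#'   models; default `FALSE`).
#' @return An object of class `evaluation_report`.
#' @export
run_loso <- function(table, clf = classifier_spec("linear_svm"),
                     sel = selection_config(), mode = c("per_fold", "global"),
                     positive = "patient", keep_models = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(c("subject_id", "group") %in% names(table)))
  groups <- unique(table$group)
  if (length(groups) != 2) stop("need exactly 2 classes, got ", length(groups))
  y <- factor(table$group, levels = c(setdiff(groups, positive), positive))
  fcols <- feature_columns(table)
  folds <- loso_folds(table$subject_id)
  global_sel <- if (!is.null(sel) && mode == "global") {
    mrmr(table, config = sel)
  }
  fold_results <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    fold <- folds[[i]]
    stopifnot(length(intersect(table$subject_id[fold$train],
                               table$subject_id[fold$test])) == 0)
    selection <- if (is.null(sel)) NULL else if (mode == "global") {
      global_sel
    } else {
      mrmr(table[fold$train, , drop = FALSE], config = sel)
    }
    use <- if (is.null(selection)) fcols else selection$ordered
    Xtr_raw <- as.matrix(table[fold$train, use, drop = FALSE])
    Xte <- as.matrix(table[fold$test, use, drop = FALSE])
    mu <- colMeans(Xtr_raw)
    sdv <- apply(Xtr_raw, 2, stats::sd)
    sdv[sdv == 0] <- 1
    standardize <- needs_standardization(clf)
    Xtr <- if (standardize) scale(Xtr_raw, mu, sdv) else Xtr_raw
    if (standardize) Xte <- scale(Xte, mu, sdv)
    fitted <- tryCatch({
      model <- fit_model(clf, Xtr, y[fold$train], fold_seed = clf$seed + i)
      list(model = model, out = predict_model(model, Xte))
    }, error = function(e) {
      stop("fold failure on held-out subject ", fold$subject, ": ",
           conditionMessage(e))
    })
    out <- fitted$out
    fold_results[[i]] <- list(
      held_out_subject = fold$subject,
      selected_features = selection,
      features = use,
      train_mean = mu,
      train_sd = sdv,
      model = if (keep_models) fitted$model,
      test_rows = fold$test,
      pred = as.character(out$pred),
      score = out$score,
      truth = as.character(y[fold$test]),
      auc = if (length(unique(y[fold$test])) == 2) {
        roc_auc(out$score, y[fold$test], positive)$auc
      } else NA_real_
    )
  }
  pooled_report(fold_results, table, positive, clf, sel, mode)
}

# Assemble the pooled evaluation_report from per-fold predictions.
pooled_report <- function(fold_results, table, positive, clf, sel, mode) {
  pred <- unlist(lapply(fold_results, `[[`, "pred"))
  truth <- unlist(lapply(fold_results, `[[`, "truth"))
  score <- unlist(lapply(fold_results, `[[`, "score"))
  subj <- unlist(lapply(fold_results, function(f) {
    rep(f$held_out_subject, length(f$truth))
  }))
  tp <- sum(pred == positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  stopifnot(tp + tn + fp + fn == nrow(table))
  roc <- roc_auc(score, truth, positive)
  per_subject <- do.call(rbind, lapply(fold_results, function(f) {
    n_ok <- sum(f$pred == f$truth)
    data.frame(subject = f$held_out_subject,
               group = f$truth[1],
               n_epochs = length(f$truth),
               n_correct = n_ok,
               p_value = binomial_subject_test(n_ok, length(f$truth)),
               majority_correct = n_ok > length(f$truth) / 2,
               auc = f$auc,
               stringsAsFactors = FALSE)
  }))
  structure(
    list(folds = fold_results,
         confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
         accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
         sensitivity = 100 * tp / (tp + fn),
         specificity = 100 * tn / (tn + fp),
         roc = roc$roc, auc = roc$auc,
         per_subject = per_subject,
         subject_accuracy = 100 * mean(per_subject$majority_correct),
         positive = positive,
         classifier = clf, selection = sel, mode = mode,
         predictions = data.frame(subject = subj, truth = truth,
                                  pred = pred, score = score,
                                  stringsAsFactors = FALSE)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, %d folds, %d pooled epochs\n",
              x$classifier$name, length(x$folds), nrow(x$predictions)))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  AUC %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$auc))
  cat(sprintf("  subject-level (majority vote) accuracy %.1f%%; %d/%d subjects beat chance (binomial p < 0.05)\n",
              x$subject_accuracy, sum(x$per_subject$p_value < 0.05),
              nrow(x$per_subject)))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Writes the pooled metrics, confusion matrix, ROC points, per-subject
#' binomial results and per-epoch predictions.
#'
#' @param report An `evaluation_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  out <- list(
    classifier = report$classifier$name,
    mode = report$mode,
    positive = report$positive,
    confusion = as.list(report$confusion),
    accuracy = report$accuracy,
    sensitivity = report$sensitivity,
    specificity = report$specificity,
    auc = report$auc,
    subject_accuracy = report$subject_accuracy,
    roc = report$roc,
    per_subject = report$per_subject,
    predictions = report$predictions
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
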