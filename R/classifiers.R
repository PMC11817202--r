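#' Specify a classifier
#'
#' Pluggable classifier contract for the evaluation harness. Learner
#' internals are delegated to established implementations (e1071 linear
#' SVM, MASS LDA, class k-nearest-neighbours, randomForest); the tested
#' surface of this package is the harness around them.
#'
#' @param name One of `"linear_svm"`, `"lda"`, `"knn"`, `"rf"`.
#' @param cost Linear-SVM regularization strength (default 1).
#' @param n_neighbors KNN neighbourhood size (default 5).
#' @param n_trees Random-forest tree count (default 500).
#' @param seed Seed applied before each (possibly stochastic) fit.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("linear_svm", "lda", "knn", "rf"),
                            cost = 1, n_neighbors = 5, n_trees = 500,
                            seed = 1) {
  name <- match.arg(name)
  stopifnot(cost > 0, n_neighbors >= 1, n_trees >= 1)
  structure(list(name = name, cost = cost,
                 n_neighbors = as.integer(n_neighbors),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "classifier_spec")
}

# TRUE for learners that expect standardized features (margin/distance
# based); random forest consumes raw features.
needs_standardization <- function(spec) spec$name != "rf"

# Fit a learner on (Xtr, ytr). ytr must be a 2-level factor whose second
# level is the positive class. Returns a fitted_classifier usable with
# predict_model(). KNN has no fitting step; the training data are stored.
fit_model <- function(spec, Xtr, ytr, fold_seed = spec$seed) {
  stopifnot(is.factor(ytr), nlevels(ytr) == 2)
  set.seed(fold_seed)
  fit <- switch(spec$name,
    linear_svm = e1071::svm(Xtr, ytr, kernel = "linear", cost = spec$cost,
                            scale = FALSE),
    lda = MASS::lda(Xtr, grouping = ytr),
    knn = list(Xtr = Xtr, ytr = ytr),
    rf = randomForest::randomForest(Xtr, ytr, ntree = spec$n_trees)
  )
  structure(list(spec = spec, fit = fit, positive = levels(ytr)[2],
                 seed = fold_seed),
            class = "fitted_classifier")
}

# Predict class labels and continuous decision scores (higher = more
# positive) for new rows.
predict_model <- function(model, X) {
  spec <- model$spec
  positive <- model$positive
  if (spec$name == "linear_svm") {
    pr <- stats::predict(model$fit, X, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # e1071 orients decision values toward the class named first in the
    # column label; flip so higher always means the positive class
    first <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
    list(pred = pr, score = unname(if (first == positive) dv else -dv))
  } else if (spec$name == "lda") {
    pr <- stats::predict(model$fit, X)
    list(pred = pr$class, score = unname(pr$posterior[, positive]))
  } else if (spec$name == "knn") {
    set.seed(model$seed) # knn breaks vote ties at random
    pr <- class::knn(model$fit$Xtr, X, model$fit$ytr,
                     k = spec$n_neighbors, prob = TRUE)
    win <- attr(pr, "prob")
    list(pred = pr,
         score = unname(ifelse(pr == positive, win, 1 - win)))
  } else { # rf
    list(pred = stats::predict(model$fit, X),
         score = unname(stats::predict(model$fit, X, type = "prob")[, positive]))
  }
}
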