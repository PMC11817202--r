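test_that("folds partition rows with one subject held out each", {
  ids <- rep(sprintf("s%d", 1:6), each = 7)
  folds <- loso_folds(ids)
  expect_length(folds, 6)
  all_test <- unlist(lapply(folds, `[[`, "test"))
  expect_equal(sort(all_test), seq_along(ids))       # union = all rows
  expect_false(any(duplicated(all_test)))            # pairwise disjoint
  for (f in folds) {
    expect_length(f$test, 7)
    expect_length(f$train, 35)
    expect_length(intersect(ids[f$train], ids[f$test]), 0)
  }
  expect_length(loso_folds(c("a", "a", "b")), 2)
  expect_error(loso_folds(rep("a", 10)), "configuration")
})

test_that("binomial subject test matches the closed form and the summation oracle", {
  expect_equal(binomial_subject_test(50, 50), 0.5^50)
  expect_equal(signif(binomial_subject_test(50, 50), 3), 8.88e-16)
  expect_equal(binomial_subject_test(0, 50), 1)
  for (k in c(20, 25, 30, 42)) {
    expect_equal(binomial_subject_test(k, 50), binom_tail_oracle(k, 50))
  }
  expect_equal(binomial_subject_test(3, 10, 0.2),
               binom_tail_oracle(3, 10, 0.2))
  expect_error(binomial_subject_test(5, 10, 1.5), "configuration")
})

test_that("AUC equals the pair-counting oracle and an external implementation", {
  labs <- c("patient", "patient", "control", "patient", "control", "control")
  sc <- c(0.9, 0.4, 0.5, 0.8, 0.2, 0.4)
  r <- roc_auc(sc, labs)
  expect_equal(r$auc, pair_count_auc(sc, labs))
  set.seed(1)
  for (i in 1:5) {
    n <- 40
    labs <- sample(rep(c("patient", "control"), n / 2))
    sc <- rnorm(n) + 0.8 * (labs == "patient")
    ours <- roc_auc(sc, labs)$auc
    expect_equal(ours, pair_count_auc(sc, labs))
    expect_equal(ours,
                 as.numeric(pROC::auc(pROC::roc(
                   labs, sc, levels = c("control", "patient"),
                   direction = "<", quiet = TRUE))))
  }
})

test_that("AUC hits its extremes and its chance level", {
  labs <- rep(c("patient", "control"), each = 10)
  expect_equal(roc_auc(as.numeric(labs == "patient"), labs)$auc, 1)
  set.seed(2)
  labs2 <- sample(rep(c("patient", "control"), 500))
  r <- roc_auc(rnorm(1000), labs2)
  expect_equal(r$auc, 0.5, tolerance = 0.05)
  expect_equal(r$roc$fpr[1], 0)
  expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
  expect_error(roc_auc(rnorm(5), rep("patient", 5)), "undefined")
})

test_that("a separable table gives perfect pooled metrics for every learner", {
  tab <- separable_table()
  for (nm in c("linear_svm", "lda", "knn", "rf")) {
    rep_ <- run_loso(tab, classifier_spec(nm, n_trees = 100), sel = NULL)
    expect_equal(rep_$accuracy, 100, info = nm)
    expect_equal(rep_$auc, 1, info = nm)
    expect_equal(sum(rep_$confusion), nrow(tab))
    expect_true(all(rep_$per_subject$p_value < 0.05))
  }
})

test_that("reversing the positive class swaps sensitivity and specificity", {
  set.seed(3)
  tab <- separable_table()
  tab$beta.activity.F3 <- tab$beta.activity.F3 + rnorm(nrow(tab), sd = 6)
  a <- run_loso(tab, classifier_spec("lda"), sel = NULL,
                positive = "patient")
  b <- run_loso(tab, classifier_spec("lda"), sel = NULL,
                positive = "control")
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("per-subject significance is consistent with the pooled predictions", {
  rep_ <- effect_report()
  ps <- rep_$per_subject
  expect_true(all(ps$n_correct <= ps$n_epochs))
  expect_equal(ps$p_value,
               mapply(binomial_subject_test, ps$n_correct, ps$n_epochs))
  expect_equal(sum(ps$n_epochs), nrow(rep_$predictions))
  expect_equal(sum(rep_$confusion), sum(ps$n_epochs))
})

test_that("selection inside folds uses training rows only", {
  rep_ <- effect_report()
  tab <- subset_features(effect_table(), bands = c("beta", "gamma"),
                         parameters = "activity")
  for (f in rep_$folds) {
    train_subjects <- tab$subject_id[setdiff(seq_len(nrow(tab)), f$test_rows)]
    expect_false(f$held_out_subject %in% train_subjects)
    expect_length(f$selected_features$ordered, 12)
    expect_false(any(duplicated(f$selected_features$ordered)))
  }
  # recomputing one fold's selection from its training rows reproduces it
  f1 <- rep_$folds[[1]]
  train_rows <- setdiff(seq_len(nrow(tab)), f1$test_rows)
  redo <- mrmr(tab[train_rows, ], config = selection_config(k = 12))
  expect_identical(redo$ordered, f1$selected_features$ordered)
})

test_that("global selection mode runs and differs structurally from per-fold", {
  tab <- subset_features(effect_table(), bands = "beta",
                         parameters = "activity")
  rep_ <- run_loso(tab, classifier_spec("lda"), selection_config(k = 5),
                   mode = "global")
  sels <- unique(lapply(rep_$folds,
                        function(f) f$selected_features$ordered))
  expect_length(sels, 1) # one shared selection across folds
})

test_that("a report serializes to JSON with its metrics intact", {
  rep_ <- effect_report()
  path <- withr::local_tempfile(fileext = ".json")
  write_evaluation_report(rep_, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$accuracy, rep_$accuracy)
  expect_equal(back$auc, rep_$auc)
  expect_equal(sum(unlist(back$confusion)), sum(rep_$confusion))
  expect_equal(nrow(back$predictions), nrow(rep_$predictions))
})
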