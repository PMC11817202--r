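test_that("LIME recovers the coefficients of a linear model", {
  set.seed(1)
  d <- 5
  beta <- c(2, -1, 0.5, 0, 3)
  predict_fn <- function(X) drop(X %*% beta)
  inst <- stats::setNames(rnorm(d), paste0("f", 1:d))
  stats_ <- list(mean = rep(0, d), sd = rep(1, d))
  ex <- lime_explain(predict_fn, inst, stats_,
                     lime_config(n_samples = 1000, seed = 3))
  w <- ex$weights[names(inst)]
  cosine <- sum(w * beta) / sqrt(sum(w^2) * sum(beta^2))
  expect_gt(cosine, 0.99)
  expect_gt(ex$r2, 0.99) # linear target: near-perfect surrogate fit
})

test_that("a constant model yields a zero, degenerate explanation", {
  inst <- stats::setNames(rnorm(4), paste0("f", 1:4))
  stats_ <- list(mean = rep(0, 4), sd = rep(1, 4))
  expect_warning(
    ex <- lime_explain(function(X) rep(1, nrow(X)), inst, stats_,
                       lime_config(n_samples = 200, seed = 1)),
    "constant")
  expect_true(ex$degenerate)
  expect_true(all(ex$weights == 0))
})

test_that("a model depending on one feature puts the largest weight there", {
  set.seed(2)
  inst <- stats::setNames(rnorm(6), paste0("f", 1:6))
  stats_ <- list(mean = rep(0, 6), sd = rep(1, 6))
  ex <- lime_explain(function(X) tanh(X[, 3]), inst, stats_,
                     lime_config(n_samples = 1000, seed = 4))
  expect_equal(names(which.max(abs(ex$weights))), "f3")
})

test_that("explanations are deterministic under a fixed seed", {
  inst <- stats::setNames(c(1, -1, 0.5), c("a", "b", "c"))
  stats_ <- list(mean = rep(0, 3), sd = rep(1, 3))
  fn <- function(X) X[, 1] - 2 * X[, 2]
  cfg <- lime_config(n_samples = 300, seed = 7)
  expect_identical(lime_explain(fn, inst, stats_, cfg),
                   lime_explain(fn, inst, stats_, cfg))
})

test_that("top_k restricts the surrogate to the most associated features", {
  set.seed(3)
  inst <- stats::setNames(rnorm(8), paste0("f", 1:8))
  stats_ <- list(mean = rep(0, 8), sd = rep(1, 8))
  ex <- lime_explain(function(X) 3 * X[, 2] + X[, 5], inst, stats_,
                     lime_config(n_samples = 1000, top_k = 2, seed = 5))
  expect_setequal(names(ex$weights), c("f2", "f5"))
})

test_that("channel aggregation handles point masses and symmetric splits", {
  mk_ex <- function(w) structure(list(weights = w, r2 = 1,
                                      degenerate = FALSE),
                                 class = "lime_explanation")
  single <- mk_ex(c(beta.activity.F3 = 0.8))
  m <- aggregate_channel_importance(list(single), "beta")
  expect_equal(m$importance[m$channel == "F3"], 1)
  expect_true(all(m$importance[m$channel != "F3"] == 0))
  split <- mk_ex(c(beta.activity.F3 = 0.5, beta.activity.F4 = -0.5))
  m2 <- aggregate_channel_importance(list(split), "beta")
  expect_equal(m2$importance[m2$channel == "F3"],
               m2$importance[m2$channel == "F4"])
  # permutation invariance over the explanation list
  exs <- list(single, split)
  m3 <- aggregate_channel_importance(exs, "beta")
  m4 <- aggregate_channel_importance(rev(exs), "beta")
  expect_equal(m3, m4)
  # weights from other bands do not leak in
  other <- mk_ex(c(gamma.activity.O1 = 5))
  m5 <- aggregate_channel_importance(list(single, other), "beta")
  expect_equal(m5$importance[m5$channel == "O1"], 0)
})

test_that("doubling the perturbation count barely moves the top channels", {
  tab <- subset_features(effect_table(), bands = c("beta", "gamma"),
                         parameters = "activity")
  rep_ <- effect_report()
  ex_small <- explain_evaluation(tab, rep_, lime_config(n_samples = 500),
                                 max_per_fold = 1)
  ex_big <- explain_evaluation(tab, rep_, lime_config(n_samples = 1000),
                               max_per_fold = 1)
  top3 <- function(exs) {
    m <- aggregate_channel_importance(exs, "beta")
    m$channel[order(-m$importance)][1:3]
  }
  a <- top3(ex_small)
  b <- top3(ex_big)
  # rankings may shuffle by at most one position
  expect_gte(length(intersect(a, b)), 2)
})

test_that("rank-sum z and p match closed cases and the enumeration oracle", {
  rs <- hjortheeg:::rank_sum_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rs$p, 0.1) # 2/20 arrangements as extreme, doubled
  expect_gt(rs$z, 0)
  set.seed(4)
  for (i in 1:6) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    x <- rnorm(n1)
    y <- rnorm(n2)
    rs <- hjortheeg:::rank_sum_test(x, y)
    expect_equal(rs$p, wilcox_enum_oracle(x, y), info = paste("rep", i))
    # z agrees with the standard normal-approximation implementation
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    expect_equal(2 * stats::pnorm(-abs(rs$z)), ref, tolerance = 1e-12)
  }
})

test_that("tie correction matches the reference implementation", {
  x <- c(1, 2, 2, 3, 5, 5, 5)
  y <- c(2, 3, 3, 4, 5, 6)
  rs <- hjortheeg:::rank_sum_test(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(rs$p, ref, tolerance = 1e-12) # ties: normal approximation
})

test_that("the z sign is positive where patients are elevated", {
  w <- wilcoxon_map(effect_table(), "activity", "beta")
  expect_gt(w$z[w$channel == "F3"], 0)
  expect_equal(w$channel, montage_channels())
  expect_true(all(w$p > 0 & w$p <= 1))
})

test_that("wilcoxon_map false-positive rate is near nominal under the null", {
  tab <- null_table()
  subj <- unique(tab$subject_id)
  set.seed(5)
  flagged <- numeric(200)
  for (i in seq_len(200)) {
    newg <- sample(rep(c("patient", "control"), length.out = length(subj)))
    tab$group <- newg[match(tab$subject_id, subj)]
    w <- wilcoxon_map(tab, "activity", "beta")
    flagged[i] <- mean(w$significant)
  }
  expect_lt(abs(mean(flagged) - 0.05), 0.03)
})

test_that("wilcoxon_map validates its inputs and supports BH adjustment", {
  tab <- effect_table()
  expect_error(wilcoxon_map(tab[tab$group == "patient", ], "activity", "beta"),
               "configuration")
  raw <- wilcoxon_map(tab, "activity", "beta")
  adj <- wilcoxon_map(tab, "activity", "beta", p_adjust = "BH")
  expect_true(all(adj$p >= raw$p - 1e-15))
})
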