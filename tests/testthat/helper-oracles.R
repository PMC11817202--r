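# Independent brute-force oracles. Each recomputes its quantity from
# first principles, without reusing the package's code paths.

# AUC by exhaustive concordant-pair counting (ties count 1/2).
pair_count_auc <- function(scores, labels, positive = "patient") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# One-sided upper binomial tail by direct summation.
binom_tail_oracle <- function(k, n, p = 0.5) {
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j),
             numeric(1)))
}

# Exact two-sided rank-sum p by enumerating every assignment of the
# pooled observations to the first group (tie-free inputs only).
wilcox_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_null <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  lo <- mean(u_null <= u_obs)
  hi <- mean(u_null >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Naive greedy mRMR: recomputes every mutual information term with an
# entropy-based estimator (H(a) + H(b) - H(a,b)) and explicit loops.
mrmr_oracle <- function(X, y, k, scheme = "MIQ", n_bins = 5) {
  ent <- function(codes) {
    p <- table(codes) / length(codes)
    -sum(p * log(p))
  }
  mi <- function(a, b) {
    ent(a) + ent(b) - ent(paste(a, b))
  }
  codes <- lapply(X, discretize, n_bins = n_bins)
  yc <- as.integer(factor(y))
  rel <- vapply(codes, mi, numeric(1), b = yc)
  chosen <- character(0)
  for (step in seq_len(k)) {
    best <- NA
    best_score <- -Inf
    for (f in names(X)) {
      if (f %in% chosen) next
      red <- if (length(chosen) == 0) 0 else {
        mean(vapply(chosen, function(s) mi(codes[[f]], codes[[s]]),
                    numeric(1)))
      }
      score <- if (scheme == "MIQ") rel[[f]] / max(red, 1e-12) else {
        rel[[f]] - red
      }
      if (score > best_score + 1e-12) { # strict improvement: first wins ties
        best_score <- score
        best <- f
      }
    }
    chosen <- c(chosen, best)
  }
  chosen
}

# Random feature table for oracle comparisons: a mix of informative and
# noise columns over two classes.
random_mrmr_instance <- function(seed, n = 60, n_feat = 6) {
  set.seed(seed)
  y <- rep(c("a", "b"), length.out = n)
  X <- as.data.frame(lapply(seq_len(n_feat), function(j) {
    signal_strength <- runif(1, 0, 1.5)
    rnorm(n) + signal_strength * (y == "a")
  }))
  names(X) <- sprintf("f%02d", seq_len(n_feat))
  list(X = X, y = y)
}
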