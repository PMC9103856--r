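# Independent brute-force oracles used across the suite. These deliberately
# use naive loops / exhaustive search, not the package's vectorized paths.

# Per-window RMS by explicit loop with the same centered window and reflect
# padding convention as the contract.
oracle_rms <- function(x, w) {
  n <- length(x)
  left <- (w - 1) %/% 2
  right <- w - 1 - left
  xp <- c(rev(x[seq_len(left) + 1]), x, rev(x[n - seq_len(right)]))
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- sqrt(mean(xp[i:(i + w - 1)]^2))
  out
}

# Majority label of each sliding window by explicit counting.
oracle_window_labels <- function(truth, w) {
  n <- length(truth)
  nw <- n - w + 1
  out <- integer(nw)
  for (i in seq_len(nw)) {
    ones <- sum(truth[i:(i + w - 1)])
    out[i] <- as.integer(ones >= w - ones) # ties -> 1
  }
  out
}

# Run cleaning by explicit scanning: flip short 1-runs, then short interior
# 0-runs.
oracle_clean_runs <- function(b, min_run) {
  runs_of <- function(v) {
    out <- list(); start <- 1
    for (i in seq_along(v)[-1]) {
      if (v[i] != v[i - 1]) {
        out[[length(out) + 1]] <- c(v[start], start, i - 1)
        start <- i
      }
    }
    out[[length(out) + 1]] <- c(v[start], start, length(v))
    out
  }
  b <- as.integer(b)
  for (r in runs_of(b)) {
    if (r[1] == 1 && (r[3] - r[2] + 1) < min_run) b[r[2]:r[3]] <- 0L
  }
  rs <- runs_of(b)
  if (length(rs) > 2) {
    for (k in 2:(length(rs) - 1)) {
      r <- rs[[k]]
      if (r[1] == 0 && (r[3] - r[2] + 1) < min_run) b[r[2]:r[3]] <- 1L
    }
  }
  b
}

# Transition scan for events, index of first sample of the new state.
oracle_events <- function(b) {
  on <- integer(0); off <- integer(0)
  for (i in seq_along(b)[-1]) {
    if (b[i] == 1 && b[i - 1] == 0) on <- c(on, i)
    if (b[i] == 0 && b[i - 1] == 1) off <- c(off, i)
  }
  list(onsets = on, offsets = off)
}

# Exhaustive optimal one-to-one matching maximizing matched pairs, breaking
# ties by smallest total |error|. Feasible for <= 4 events per side.
oracle_optimal_match <- function(pred_ms, truth_ms, tol) {
  np <- length(pred_ms); nt <- length(truth_ms)
  best <- list(n = -1, cost = Inf)
  assign_rec <- function(p, used_t, n, cost) {
    if (p > np) {
      if (n > best$n || (n == best$n && cost < best$cost)) {
        best <<- list(n = n, cost = cost)
      }
      return(invisible())
    }
    assign_rec(p + 1, used_t, n, cost) # leave pred p unmatched
    for (t in seq_len(nt)) {
      d <- abs(pred_ms[p] - truth_ms[t])
      if (!used_t[t] && d < tol) {
        used_t[t] <- TRUE
        assign_rec(p + 1, used_t, n + 1, cost + d)
        used_t[t] <- FALSE
      }
    }
  }
  if (np == 0 || nt == 0) return(list(n = 0, cost = 0))
  assign_rec(1, logical(nt), 0, 0)
  best
}

# Confusion-matrix metrics by explicit counting.
oracle_sample_metrics <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
    if (pred[i] == 0 && truth[i] == 0) tn <- tn + 1
  }
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) 100 * tp / (tp + fp) else if (tp + fn == 0) 100 else 0
    r <- if (tp + fn > 0) 100 * tp / (tp + fn) else if (tp + fp == 0) 100 else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else if (tp + fp + fn == 0) 100 else 0
    c(p, r, f)
  }
  act <- prf(tp, fp, fn)
  sil <- prf(tn, fn, fp)
  n1 <- tp + fn; n0 <- tn + fp
  list(accuracy = 100 * (tp + tn) / length(pred),
       activity = act, silent = sil,
       macro_f1 = (act[3] + sil[3]) / 2,
       weighted_f1 = (act[3] * n1 + sil[3] * n0) / (n0 + n1))
}

# A small two-blob linearly separable windowed dataset for training oracles.
make_separable_windows <- function(n = 2000, dim = 4, seed = 42) {
  set.seed(seed)
  n1 <- n %/% 2
  X <- rbind(matrix(stats::rnorm(n1 * dim, mean = 2, sd = 0.3), ncol = dim),
             matrix(stats::rnorm((n - n1) * dim, mean = -2, sd = 0.3),
                    ncol = dim))
  y <- c(rep(1L, n1), rep(0L, n - n1))
  perm <- sample.int(n)
  list(X = X[perm, ], y = y[perm])
}
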