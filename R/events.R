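# Event post-processing: run-length cleaning of the per-sample binary
# output, transition scanning into onset/offset events, and one-to-one
# tolerance matching against ground truth.

#' Remove physiologically implausible short runs
#'
#' Two passes over the run-length encoding: first every run of 1s shorter
#' than `min_run` samples is flipped to 0 (activations shorter than 30 ms at
#' 2000 Hz do not control joint motion), then every *interior* run of 0s
#' shorter than `min_run` is flipped to 1 (brief drop-outs inside an
#' activation are bridged). Leading and trailing silent runs are never
#' converted to activity. The pass order matters on adjacent short runs and
#' is fixed as stated.
#'
#' @param binary Integer/logical 0-1 vector.
#' @param min_run Minimum plausible run length in samples (60 = 30 ms at
#'   2000 Hz).
#' @return Cleaned integer 0/1 vector with no interior run shorter than
#'   `min_run`.
#' @export
clean_runs <- function(binary, min_run = 60) {
  stopifnot(min_run >= 1)
  b <- as.integer(binary)
  if (length(b) == 0) return(b)
  r <- rle(b)
  r$values[r$values == 1L & r$lengths < min_run] <- 0L
  b <- inverse.rle(r)
  r <- rle(b)
  k <- length(r$values)
  if (k > 2) {
    interior <- seq(2, k - 1)
    flip <- interior[r$values[interior] == 0L & r$lengths[interior] < min_run]
    r$values[flip] <- 1L
    b <- inverse.rle(r)
  }
  b
}

#' Extract onset/offset events from a binary activity sequence
#'
#' Scans the sequence chronologically: each 0-to-1 transition is an onset
#' (index of the first active sample), each 1-to-0 transition an offset
#' (index of the first silent sample). A run of 1s touching the start of the
#' signal yields no onset, one touching the end no offset, because no
#' transition is observed.
#'
#' @param binary Integer/logical 0-1 vector (normally cleaned with
#'   [clean_runs()]).
#' @param fs_hz Sampling frequency, Hz.
#' @return Object of class `event_list`: list with `onsets` and `offsets`
#'   (1-based sample indices) and `fs_hz`.
#' @export
extract_events <- function(binary, fs_hz = 2000) {
  b <- as.integer(binary)
  d <- diff(b)
  structure(list(onsets = which(d == 1L) + 1L,
                 offsets = which(d == -1L) + 1L,
                 fs_hz = fs_hz),
            class = "event_list")
}

#' Event times in milliseconds
#'
#' Converts the 1-based sample indices of an [extract_events()] list to
#' times in ms (sample 1 is time 0).
#'
#' @param events An `event_list`.
#' @param kind `"onset"` or `"offset"`.
#' @return Numeric vector of times in ms.
#' @export
event_times_ms <- function(events, kind = c("onset", "offset")) {
  kind <- match.arg(kind)
  idx <- if (kind == "onset") events$onsets else events$offsets
  (idx - 1) / events$fs_hz * 1000
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d onsets, %d offsets @ %g Hz\n",
              length(x$onsets), length(x$offsets), x$fs_hz))
  invisible(x)
}

# Optimal one-to-one matching of two sorted time vectors (ms): maximizes
# the number of pairs with |dt| < tol, then minimizes total |dt|. Because
# both sequences are chronologically ordered and the feasibility window is
# an interval, an optimal matching that preserves order exists (uncrossing
# two crossed pairs never increases total |dt| nor breaks feasibility), so
# an O(np * nt) dynamic program over (pred, truth) prefixes is exact.
optimal_match_times <- function(pred_ms, truth_ms, tolerance_ms) {
  np <- length(pred_ms); nt <- length(truth_ms)
  empty <- data.frame(pred = integer(0), truth = integer(0),
                      error_ms = numeric(0))
  if (np == 0 || nt == 0) return(empty)
  op <- order(pred_ms); ot <- order(truth_ms)
  p <- pred_ms[op]; tt <- truth_ms[ot]
  cnt <- matrix(0L, np + 1, nt + 1)
  cost <- matrix(0, np + 1, nt + 1)
  move <- matrix(0L, np + 1, nt + 1) # 1 = skip pred, 2 = skip truth, 3 = pair
  for (i in seq_len(np)) {
    for (j in seq_len(nt)) {
      bc <- cnt[i, j + 1]; bw <- cost[i, j + 1]; mv <- 1L
      if (cnt[i + 1, j] > bc ||
          (cnt[i + 1, j] == bc && cost[i + 1, j] < bw)) {
        bc <- cnt[i + 1, j]; bw <- cost[i + 1, j]; mv <- 2L
      }
      d <- abs(p[i] - tt[j])
      if (d < tolerance_ms) {
        pc <- cnt[i, j] + 1L; pw <- cost[i, j] + d
        if (pc > bc || (pc == bc && pw < bw)) {
          bc <- pc; bw <- pw; mv <- 3L
        }
      }
      cnt[i + 1, j + 1] <- bc
      cost[i + 1, j + 1] <- bw
      move[i + 1, j + 1] <- mv
    }
  }
  keep_p <- integer(0); keep_t <- integer(0)
  i <- np; j <- nt
  while (i > 0 && j > 0) {
    mv <- move[i + 1, j + 1]
    if (mv == 3L) {
      keep_p <- c(op[i], keep_p); keep_t <- c(ot[j], keep_t)
      i <- i - 1; j <- j - 1
    } else if (mv == 1L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  data.frame(pred = keep_p, truth = keep_t,
             error_ms = pred_ms[keep_p] - truth_ms[keep_t])
}

#' Match predicted events to ground-truth events under tolerance
#'
#' Onsets are matched only to onsets and offsets only to offsets. The
#' one-to-one assignment maximizes the number of matched pairs and, among
#' such assignments, minimizes the total absolute time difference (an exact
#' order-preserving dynamic program); a pair is a true positive iff
#' `|t_truth - t_pred| < tolerance_ms` (strict). Unmatched
#' predictions are false positives, unmatched truths false negatives. The
#' signed error of a pair is `t_pred - t_truth` (positive = predicted late).
#'
#' @param predicted,truth `event_list` objects with the same `fs_hz`.
#' @param tolerance_ms Matching tolerance in ms (default 100).
#' @return Object of class `event_match`: list with `pairs` (data frame
#'   `kind`, `pred_index`, `truth_index`, `error_ms`), per-kind `fp` and
#'   `fn` counts, and `tolerance_ms`.
#' @export
match_events <- function(predicted, truth, tolerance_ms = 100) {
  stopifnot(inherits(predicted, "event_list"), inherits(truth, "event_list"))
  if (!isTRUE(all.equal(predicted$fs_hz, truth$fs_hz))) {
    stop("predicted and truth event lists have different sampling rates")
  }
  out_pairs <- list()
  fp <- c(onset = 0L, offset = 0L)
  fn <- c(onset = 0L, offset = 0L)
  for (kind in c("onset", "offset")) {
    pm <- event_times_ms(predicted, kind)
    tm <- event_times_ms(truth, kind)
    m <- optimal_match_times(pm, tm, tolerance_ms)
    fp[[kind]] <- length(pm) - nrow(m)
    fn[[kind]] <- length(tm) - nrow(m)
    if (nrow(m) > 0) {
      idx_p <- if (kind == "onset") predicted$onsets else predicted$offsets
      idx_t <- if (kind == "onset") truth$onsets else truth$offsets
      out_pairs[[kind]] <- data.frame(kind = kind,
                                      pred_index = idx_p[m$pred],
                                      truth_index = idx_t[m$truth],
                                      error_ms = m$error_ms)
    }
  }
  pairs <- if (length(out_pairs)) do.call(rbind, out_pairs) else
    data.frame(kind = character(0), pred_index = integer(0),
               truth_index = integer(0), error_ms = numeric(0))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, fp = fp, fn = fn,
                 tolerance_ms = tolerance_ms),
            class = "event_match")
}

#' Serialize an event list to JSON
#'
#' Times are written both as 0-based sample indices and in ms.
#'
#' @param events An `event_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_json <- function(events, path) {
  obj <- list(fs_hz = events$fs_hz,
              onsets_sample = events$onsets - 1L,
              offsets_sample = events$offsets - 1L,
              onsets_ms = event_times_ms(events, "onset"),
              offsets_ms = event_times_ms(events, "offset"))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
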