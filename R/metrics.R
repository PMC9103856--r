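# Performance measures: per-sample classification scores (class-wise
# precision/recall/F1, accuracy, macro and support-weighted F1), event-level
# precision/recall/F1 from tolerance matching, timing MAE and bias, and
# stratified mean +/- SD reports.

# 0/0 convention: a ratio with empty denominator is 100% when there is
# nothing to find and nothing was claimed, 0% otherwise.
safe_ratio <- function(num, den, empty_both) {
  if (den == 0) return(if (empty_both) 100 else 0)
  100 * num / den
}

prf_from_counts <- function(tp, fp, fn) {
  empty <- (tp + fp + fn) == 0
  precision <- safe_ratio(tp, tp + fp, empty)
  recall <- safe_ratio(tp, tp + fn, empty)
  f1 <- if (precision + recall == 0) {
    if (empty) 100 else 0
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1)
}

#' Per-sample classification metrics
#'
#' Confusion-matrix scores of a binary per-sample prediction against the
#' ground truth, reported separately with activity (1) and silent (0) as the
#' positive class, plus overall accuracy, macro F1 (unweighted mean of the
#' two class F1s) and support-weighted F1 (weighted by the number of truth
#' samples in each class). All values are percentages.
#'
#' @param predicted,truth Equal-length 0/1 vectors.
#' @return List with `accuracy`, `activity` and `silent` (each
#'   `precision`/`recall`/`f1`), `macro_f1`, `weighted_f1`, `support`
#'   (named truth counts).
#' @export
sample_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length")
  }
  p <- as.integer(predicted); g <- as.integer(truth)
  tp1 <- sum(p == 1L & g == 1L); fp1 <- sum(p == 1L & g == 0L)
  fn1 <- sum(p == 0L & g == 1L); tn1 <- sum(p == 0L & g == 0L)
  activity <- prf_from_counts(tp1, fp1, fn1)
  silent <- prf_from_counts(tn1, fn1, fp1)
  n1 <- tp1 + fn1; n0 <- tn1 + fp1
  weighted <- if (n0 + n1 > 0) {
    (activity$f1 * n1 + silent$f1 * n0) / (n0 + n1)
  } else 100
  list(accuracy = 100 * mean(p == g),
       activity = activity, silent = silent,
       macro_f1 = (activity$f1 + silent$f1) / 2,
       weighted_f1 = weighted,
       support = c(activity = n1, silent = n0))
}

#' Event-level precision, recall and F1
#'
#' Computed per event kind from the true-positive pairs and the
#' false-positive / false-negative counts of an [match_events()] result.
#'
#' @param match An `event_match`.
#' @return List with `onset` and `offset`, each holding
#'   `precision`/`recall`/`f1` in percent.
#' @export
event_metrics <- function(match) {
  stopifnot(inherits(match, "event_match"))
  out <- list()
  for (kind in c("onset", "offset")) {
    tp <- sum(match$pairs$kind == kind)
    out[[kind]] <- prf_from_counts(tp, match$fp[[kind]], match$fn[[kind]])
  }
  out
}

#' Mean absolute timing error of matched events
#'
#' Average of `|t_pred - t_truth|` over true-positive pairs of the given
#' kind; `NA` (not 0) when no pair was matched.
#'
#' @param match An `event_match`.
#' @param kind `"onset"`, `"offset"`, or `"both"` to pool kinds.
#' @return MAE in ms, or `NA_real_`.
#' @export
event_mae <- function(match, kind = c("onset", "offset", "both")) {
  kind <- match.arg(kind)
  e <- if (kind == "both") match$pairs$error_ms else
    match$pairs$error_ms[match$pairs$kind == kind]
  if (length(e) == 0) return(NA_real_)
  mean(abs(e))
}

#' Mean signed timing error (bias) of matched events
#'
#' Negative values mean the prediction anticipates the ground-truth event,
#' positive values that it lags.
#'
#' @inheritParams event_mae
#' @return Bias in ms, or `NA_real_`.
#' @export
event_bias <- function(match, kind = c("onset", "offset", "both")) {
  kind <- match.arg(kind)
  e <- if (kind == "both") match$pairs$error_ms else
    match$pairs$error_ms[match$pairs$kind == kind]
  if (length(e) == 0) return(NA_real_)
  mean(e)
}

#' Stratified mean +/- SD report of per-signal metrics
#'
#' Joins a per-signal metrics table to the dataset manifest and aggregates
#' each numeric metric as mean and SD, by SNR and by (sigma, alpha, SNR)
#' cell, plus a pooled row. Per-signal averaging (not sample pooling) is the
#' default aggregation throughout the package.
#'
#' @param results Data frame with one row per signal, a column `id`, and
#'   numeric metric columns.
#' @param manifest Manifest data frame from [generate_dataset()] covering
#'   every `id` in `results`.
#' @return List of data frames `by_snr`, `by_cell`, `pooled`; each metric
#'   contributes `<name>_mean` and `<name>_sd` columns.
#' @export
stratified_report <- function(results, manifest) {
  stopifnot(is.data.frame(results), "id" %in% names(results))
  if (!all(results$id %in% manifest$id)) {
    stop("results contain signal ids missing from the manifest")
  }
  key <- manifest[match(results$id, manifest$id),
                  c("sigma_s", "alpha", "snr_db")]
  df <- cbind(key, results[setdiff(names(results), "id")])
  metric_cols <- names(df)[vapply(df, is.numeric, logical(1))]
  metric_cols <- setdiff(metric_cols, c("sigma_s", "alpha", "snr_db"))
  agg <- function(by) {
    means <- stats::aggregate(df[metric_cols], by = by, FUN = mean,
                              na.rm = TRUE)
    sds <- stats::aggregate(df[metric_cols], by = by,
                            FUN = function(x) {
                              x <- x[!is.na(x)]
                              if (length(x) <= 1) 0 else stats::sd(x)
                            })
    names(means)[names(means) %in% metric_cols] <-
      paste0(metric_cols, "_mean")
    names(sds)[names(sds) %in% metric_cols] <- paste0(metric_cols, "_sd")
    merge(means, sds)
  }
  pooled <- data.frame(t(c(vapply(df[metric_cols], mean, numeric(1),
                                  na.rm = TRUE),
                           vapply(df[metric_cols],
                                  function(x) stats::sd(x[!is.na(x)]),
                                  numeric(1)))))
  names(pooled) <- c(paste0(metric_cols, "_mean"), paste0(metric_cols, "_sd"))
  list(by_snr = agg(list(snr_db = df$snr_db)),
       by_cell = agg(list(sigma_s = df$sigma_s, alpha = df$alpha,
                          snr_db = df$snr_db)),
       pooled = pooled)
}
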