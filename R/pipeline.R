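# End-to-end glue: featurize whole datasets, apply a trained detector to a
# signal, score per-signal detections, and run the full
# simulate -> featurize -> train -> detect -> evaluate pipeline from a YAML
# config.

#' Featurize one signal into a labeled windowed dataset
#'
#' Band-pass conditions the raw signal (10-500 Hz), builds the selected
#' feature channels and segments them into labeled 10-sample windows.
#'
#' @param x Numeric samples or a `semg_signal`.
#' @param ground_truth Per-sample 0/1 labels; taken from the signal object
#'   when omitted. Use a vector of zeros for unlabeled inference input.
#' @param fs_hz Sampling rate; taken from the signal object when omitted.
#' @param channels Feature subset, see [build_feature_matrix()].
#' @param window_len Window length in samples.
#' @param ... Passed to [build_feature_matrix()].
#' @return A `windowed_dataset`.
#' @export
featurize_signal <- function(x, ground_truth = NULL, fs_hz = NULL,
                             channels = c("le", "rms", "cwt"),
                             window_len = 10, ...) {
  if (inherits(x, "semg_signal")) {
    if (is.null(fs_hz)) fs_hz <- x$params$fs_hz
    if (is.null(ground_truth)) ground_truth <- x$ground_truth
    x <- x$samples
  }
  if (is.null(fs_hz)) stop("fs_hz is required for plain numeric input")
  if (is.null(ground_truth)) ground_truth <- integer(length(x))
  filtered <- bandpass_semg(x, fs_hz)
  fm <- build_feature_matrix(filtered, fs_hz, channels = channels, ...)
  window_and_label(fm, ground_truth, window_len)
}

#' Featurize every signal of a dataset
#'
#' Applies [featurize_signal()] to each signal and stacks the flattened
#' windows into one preallocated design matrix, stored transposed (one
#' column per window) so that minibatch gathering during training touches
#' contiguous memory and no intermediate per-signal copies survive.
#'
#' @param dataset A `semg_dataset`.
#' @param channels,window_len,... Passed to [featurize_signal()].
#' @return Object of class `semg_features`: list with `Xt` (features x
#'   windows matrix), `y` (labels), `signal_id` (manifest id per window),
#'   `anchor_index` (per-window anchor sample), `n_samples` (per-signal
#'   length vector), `fs_hz`.
#' @export
featurize_dataset <- function(dataset, channels = c("le", "rms", "cwt"),
                              window_len = 10, ...) {
  stopifnot(inherits(dataset, "semg_dataset"))
  nsig <- length(dataset$signals)
  n_samples <- vapply(dataset$signals, function(s) length(s$samples),
                      integer(1))
  nw <- n_samples - window_len + 1
  total <- sum(nw)
  offsets <- cumsum(c(0, nw[-nsig]))
  Xt <- NULL
  y <- integer(total)
  anchor <- integer(total)
  for (i in seq_len(nsig)) {
    wd <- featurize_signal(dataset$signals[[i]], channels = channels,
                           window_len = window_len, ...)
    if (is.null(Xt)) Xt <- matrix(0, ncol(wd$windows), total)
    cols <- offsets[i] + seq_len(nw[i])
    Xt[, cols] <- t(wd$windows)
    y[cols] <- wd$labels
    anchor[cols] <- wd$anchor_index
  }
  structure(list(Xt = Xt, y = y,
                 signal_id = rep(dataset$manifest$id, times = nw),
                 anchor_index = anchor,
                 n_samples = n_samples,
                 fs_hz = dataset$spec$fs_hz),
            class = "semg_features")
}

#' Detect muscle activity in one signal with a trained model
#'
#' Featurizes the signal, predicts per-window probabilities, thresholds
#' them, spreads the window decisions back onto samples and applies the
#' minimum-duration run cleaning.
#'
#' @param x Numeric samples or a `semg_signal`.
#' @param model A trained `semg_model`.
#' @param fs_hz Sampling rate; taken from the signal object when omitted.
#' @param channels Feature subset the model was trained on.
#' @param min_run Minimum plausible run length in samples for
#'   [clean_runs()]; `0` disables cleaning.
#' @param ... Passed to [featurize_signal()].
#' @return Integer 0/1 vector, one value per sample.
#' @export
detect_activity <- function(x, model, fs_hz = NULL,
                            channels = c("le", "rms", "cwt"), min_run = 60,
                            ...) {
  if (inherits(x, "semg_signal") && is.null(fs_hz)) fs_hz <- x$params$fs_hz
  wd <- featurize_signal(x, ground_truth = NULL, fs_hz = fs_hz,
                         channels = channels, ...)
  n <- if (inherits(x, "semg_signal")) length(x$samples) else length(x)
  pr <- predict_proba(model, wd)
  b <- windows_to_samples(binarize(pr, model$config$threshold),
                          wd$anchor_index, n)
  if (min_run > 0) b <- clean_runs(b, min_run) else b <- as.integer(b)
  b
}

#' Score one per-sample detection against its ground truth
#'
#' Computes the sample-level classification metrics and, after extracting
#' events from both sequences, the event-level scores, MAE and bias per
#' event kind.
#'
#' @param predicted,truth Per-sample 0/1 vectors (the prediction is assumed
#'   already cleaned).
#' @param fs_hz Sampling rate, Hz.
#' @param tolerance_ms Event-matching tolerance.
#' @return List with `samples` ([sample_metrics()] output), `events`
#'   ([event_metrics()] output), `mae`, `bias` (named onset/offset vectors,
#'   `NA` when no pair matched), and `match` (the `event_match`).
#' @export
evaluate_detection <- function(predicted, truth, fs_hz = 2000,
                               tolerance_ms = 100) {
  sm <- sample_metrics(predicted, truth)
  ev_p <- extract_events(predicted, fs_hz)
  ev_t <- extract_events(truth, fs_hz)
  match <- match_events(ev_p, ev_t, tolerance_ms)
  em <- event_metrics(match)
  list(samples = sm, events = em,
       mae = c(onset = event_mae(match, "onset"),
               offset = event_mae(match, "offset")),
       bias = c(onset = event_bias(match, "onset"),
                offset = event_bias(match, "offset")),
       match = match)
}

# Flatten evaluate_detection output into a one-row data frame.
detection_row <- function(id, ev) {
  data.frame(id = id,
             accuracy = ev$samples$accuracy,
             act_precision = ev$samples$activity$precision,
             act_recall = ev$samples$activity$recall,
             act_f1 = ev$samples$activity$f1,
             sil_precision = ev$samples$silent$precision,
             sil_recall = ev$samples$silent$recall,
             sil_f1 = ev$samples$silent$f1,
             macro_f1 = ev$samples$macro_f1,
             weighted_f1 = ev$samples$weighted_f1,
             onset_precision = ev$events$onset$precision,
             onset_recall = ev$events$onset$recall,
             onset_f1 = ev$events$onset$f1,
             offset_precision = ev$events$offset$precision,
             offset_recall = ev$events$offset$recall,
             offset_f1 = ev$events$offset$f1,
             mae_onset = ev$mae[["onset"]],
             mae_offset = ev$mae[["offset"]],
             bias_onset = ev$bias[["onset"]],
             bias_offset = ev$bias[["offset"]])
}

#' Train on one dataset and evaluate on another
#'
#' The core experiment: featurizes both datasets, trains the classifier on
#' the training windows, predicts the test windows in one pass, converts
#' each signal's window decisions to cleaned per-sample activity, and scores
#' every test signal. Pre-featurized inputs (from [featurize_dataset()]) can
#' be supplied to reuse features across seeds or model kinds.
#'
#' @param train_data A `semg_dataset` or a [featurize_dataset()] result.
#' @param test_data A `semg_dataset` (required for ground truth and the
#'   manifest).
#' @param config A [train_config()].
#' @param channels Feature subset.
#' @param min_run Run-cleaning threshold in samples.
#' @param tolerance_ms Event-matching tolerance.
#' @param test_features Optional pre-computed [featurize_dataset()] result
#'   for `test_data`.
#' @return List with `model`, `per_signal` (data frame, one row per test
#'   signal), `pairs` (data frame of matched event pairs: `id`, `kind`,
#'   `error_ms`), `manifest`.
#' @export
run_experiment <- function(train_data, test_data, config = train_config(),
                           channels = c("le", "rms", "cwt"), min_run = 60,
                           tolerance_ms = 100, test_features = NULL) {
  tr <- if (inherits(train_data, "semg_dataset")) {
    featurize_dataset(train_data, channels = channels)
  } else train_data
  te <- if (is.null(test_features)) {
    featurize_dataset(test_data, channels = channels)
  } else test_features
  model <- train_classifier(tr, config)
  prob <- predict_proba(model, te)
  pred_win <- binarize(prob, config$threshold)
  fs <- te$fs_hz
  ids <- unique(te$signal_id)
  rows <- vector("list", length(ids))
  pair_list <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    sel <- te$signal_id == id
    n <- te$n_samples[[j]]
    b <- windows_to_samples(pred_win[sel], te$anchor_index[sel], n)
    if (min_run > 0) b <- clean_runs(b, min_run)
    truth <- test_data$signals[[j]]$ground_truth
    ev <- evaluate_detection(b, truth, fs, tolerance_ms)
    rows[[j]] <- detection_row(id, ev)
    if (nrow(ev$match$pairs) > 0) {
      pair_list[[j]] <- data.frame(id = id, kind = ev$match$pairs$kind,
                                   error_ms = ev$match$pairs$error_ms)
    }
  }
  pairs <- do.call(rbind, pair_list[!vapply(pair_list, is.null, logical(1))])
  if (is.null(pairs)) {
    pairs <- data.frame(id = integer(0), kind = character(0),
                        error_ms = numeric(0))
  }
  list(model = model, per_signal = do.call(rbind, rows), pairs = pairs,
       manifest = test_data$manifest)
}

# Tiny FNV-1a hash of a string, for run-log config fingerprints.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate, featurize, train, detect and evaluate, writing
#' all artifacts (dataset manifests, trained model, per-signal events,
#' stratified metric tables, run log) under `out_dir`. The configuration is
#' a YAML file or an equivalent named list with optional sections
#' `train_grid` (`reps`, `seed`), `test_grid` (`reps`, `seed`, `snrs_db`),
#' `features` (`channels`), `train` (any [train_config()] argument),
#' `detector` (`method`: `"mlp"`, `"svm_linear"` or `"dt"`), `events`
#' (`min_run`, `tolerance_ms`).
#'
#' @param config Path to a YAML file, or a named list.
#' @param out_dir Output directory.
#' @return The stratified report (invisibly); artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  get_cfg <- function(section, key, default) {
    v <- cfg[[section]][[key]]
    if (is.null(v)) default else v
  }
  method <- get_cfg("detector", "method", "mlp")
  channels <- get_cfg("features", "channels", c("le", "rms", "cwt"))
  min_run <- get_cfg("events", "min_run", 60)
  tolerance_ms <- get_cfg("events", "tolerance_ms", 100)

  tr_spec <- training_grid(reps = get_cfg("train_grid", "reps", 8),
                           seed = get_cfg("train_grid", "seed", 1L))
  te_spec <- test_grid(reps = get_cfg("test_grid", "reps", 8),
                       seed = get_cfg("test_grid", "seed", 2L))
  snrs <- cfg$test_grid$snrs_db
  if (!is.null(snrs)) te_spec$snrs_db <- snrs
  tr_snrs <- cfg$train_grid$snrs_db
  if (!is.null(tr_snrs)) tr_spec$snrs_db <- tr_snrs

  test_ds <- generate_dataset(te_spec)
  utils::write.csv(test_ds$manifest, file.path(out_dir, "test_manifest.csv"),
                   row.names = FALSE)

  if (method == "dt") {
    dtc <- dt_config(m = get_cfg("detector", "m", 5),
                     r0 = get_cfg("detector", "r0", 1),
                     false_alarm_prob = get_cfg("detector",
                                                "false_alarm_prob", 0.05))
    rows <- vector("list", length(test_ds$signals))
    for (j in seq_along(test_ds$signals)) {
      sig <- test_ds$signals[[j]]
      b <- detect_dt(sig$samples, sig$params$fs_hz, dtc,
                     noise_var = sig$params$noise_var)
      ev <- evaluate_detection(b, sig$ground_truth, sig$params$fs_hz,
                               tolerance_ms)
      rows[[j]] <- detection_row(test_ds$manifest$id[j], ev)
    }
    per_signal <- do.call(rbind, rows)
  } else {
    train_ds <- generate_dataset(tr_spec)
    utils::write.csv(train_ds$manifest,
                     file.path(out_dir, "train_manifest.csv"),
                     row.names = FALSE)
    tc <- train_config(
      hidden_units = get_cfg("train", "hidden_units", 32),
      learning_rate = get_cfg("train", "learning_rate", 0.001),
      batch_size = get_cfg("train", "batch_size", 512),
      epochs = get_cfg("train", "epochs", 40),
      l2_penalty = get_cfg("train", "l2_penalty", 1e-4),
      threshold = get_cfg("train", "threshold", 0.5),
      seed = get_cfg("train", "seed", 1L),
      model_kind = method)
    res <- run_experiment(train_ds, test_ds, tc, channels = channels,
                          min_run = min_run, tolerance_ms = tolerance_ms)
    save_model(res$model, file.path(out_dir, "model.json"))
    per_signal <- res$per_signal
    utils::write.csv(res$pairs, file.path(out_dir, "event_pairs.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(per_signal, file.path(out_dir, "per_signal_metrics.csv"),
                   row.names = FALSE)
  report <- stratified_report(per_signal, test_ds$manifest)
  utils::write.csv(report$by_snr, file.path(out_dir, "metrics_by_snr.csv"),
                   row.names = FALSE)
  utils::write.csv(report$by_cell, file.path(out_dir, "metrics_by_cell.csv"),
                   row.names = FALSE)
  log <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              config = cfg,
              config_hash = fnv1a_hash(jsonlite::toJSON(cfg,
                                                        auto_unbox = TRUE)),
              seeds = list(train = tr_spec$seed, test = te_spec$seed,
                           model = get_cfg("train", "seed", 1L)),
              package_version = as.character(utils::packageVersion("emgonset")))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
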