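# Plain-text I/O: single signals as 2-column CSV with the sampling rate in
# a header comment, datasets as a directory bundle (manifest + samples +
# ground truth as CSV).

#' Write a signal to CSV
#'
#' Two columns (`time_s`, `amplitude`) preceded by a `# fs_hz=<rate>` header
#' comment; amplitudes are written with 17 significant digits so the file
#' round-trips bitwise through [read_signal()].
#'
#' @param x Numeric samples or a `semg_signal`.
#' @param path Output path.
#' @param fs_hz Sampling rate; taken from the signal object when omitted.
#' @param channel_label Optional label stored in the header.
#' @return `path`, invisibly.
#' @export
write_signal <- function(x, path, fs_hz = NULL, channel_label = NULL) {
  if (inherits(x, "semg_signal")) {
    if (is.null(fs_hz)) fs_hz <- x$params$fs_hz
    x <- x$samples
  }
  if (is.null(fs_hz)) stop("fs_hz is required for plain numeric input")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g", fs_hz), con)
  if (!is.null(channel_label)) {
    writeLines(sprintf("# channel=%s", channel_label), con)
  }
  writeLines("time_s,amplitude", con)
  t <- (seq_along(x) - 1) / fs_hz
  writeLines(sprintf("%.17g,%.17g", t, x), con)
  invisible(path)
}

#' Read a signal written by [write_signal()]
#'
#' Parses the `# fs_hz=` header comment (an explicit error is raised when it
#' is absent and no sidecar metadata is given) and the `time_s`/`amplitude`
#' columns; a non-numeric row is reported with its line number.
#'
#' @param path CSV file path.
#' @param fs_hz Sampling rate override when the file lacks the header.
#' @return Object of class `signal_record`: list with `samples`, `fs_hz`,
#'   `channel_label`.
#' @export
read_signal <- function(path, fs_hz = NULL) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  rate_line <- grep("^# *fs_hz *=", header, value = TRUE)
  if (length(rate_line) > 0) {
    fs_hz <- as.numeric(sub("^# *fs_hz *= *", "", rate_line[1]))
  }
  if (is.null(fs_hz) || is.na(fs_hz)) {
    stop("sampling rate not found: file has no '# fs_hz=' header and no ",
         "fs_hz was supplied")
  }
  label_line <- grep("^# *channel *=", header, value = TRUE)
  channel_label <- if (length(label_line)) {
    sub("^# *channel *= *", "", label_line[1])
  } else NA_character_
  body <- lines[!grepl("^#", lines)]
  if (length(body) == 0) stop("no data rows in ", path)
  has_header <- grepl("amplitude", body[1])
  first_row <- if (has_header) 2L else 1L
  rows <- body[seq(first_row, length(body))]
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, ",", fixed = TRUE)
  ncol <- length(parts[[1]])
  amp_col <- if (ncol >= 2) 2L else 1L
  amp <- vapply(seq_along(parts), function(i) {
    v <- suppressWarnings(as.numeric(parts[[i]][amp_col]))
    if (is.na(v)) {
      stop(sprintf("non-numeric amplitude at line %d of %s",
                   i + first_row - 1 + length(header), path))
    }
    v
  }, numeric(1))
  structure(list(samples = amp, fs_hz = fs_hz,
                 channel_label = channel_label),
            class = "signal_record")
}

#' Write a simulated dataset bundle
#'
#' Creates `dir` with `manifest.csv` (one row per signal), `samples.csv`
#' and `ground_truth.csv` (one column per signal), and `spec.json`.
#'
#' @param dataset A `semg_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "semg_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  S <- vapply(dataset$signals, `[[`, numeric(length(dataset$signals[[1]]$samples)),
              "samples")
  G <- vapply(dataset$signals, `[[`,
              integer(length(dataset$signals[[1]]$ground_truth)),
              "ground_truth")
  utils::write.csv(S, file.path(dir, "samples.csv"), row.names = FALSE)
  utils::write.csv(G, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(dataset$spec), file.path(dir, "spec.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dataset bundle written by [write_dataset()]
#'
#' @param dir Directory produced by [write_dataset()].
#' @return A `semg_dataset` (signal `envelope` entries are not stored on
#'   disk and are returned as `NULL`).
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  S <- as.matrix(utils::read.csv(file.path(dir, "samples.csv")))
  G <- as.matrix(utils::read.csv(file.path(dir, "ground_truth.csv")))
  sp <- jsonlite::read_json(file.path(dir, "spec.json"),
                            simplifyVector = TRUE)
  snr_ref <- if (is.null(sp$snr_ref)) "window" else sp$snr_ref
  spec <- dataset_spec(sigmas_s = sp$sigmas_s, alphas = sp$alphas,
                       snrs_db = sp$snrs_db, reps = sp$reps, seed = sp$seed,
                       fs_hz = sp$fs_hz, duration_s = sp$duration_s,
                       noise_var = sp$noise_var, snr_ref = snr_ref)
  signals <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- sim_params(sigma_s = manifest$sigma_s[i], alpha = manifest$alpha[i],
                    snr_db = manifest$snr_db[i], mu_s = manifest$mu_s[i],
                    fs_hz = sp$fs_hz, duration_s = sp$duration_s,
                    noise_var = sp$noise_var, seed = manifest$seed[i],
                    snr_ref = snr_ref)
    structure(list(samples = unname(S[, i]),
                   ground_truth = as.integer(G[, i]),
                   envelope = NULL, params = p),
              class = "semg_signal")
  })
  structure(list(signals = signals, manifest = manifest, spec = spec),
            class = "semg_dataset")
}
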