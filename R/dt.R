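# Double-threshold statistical baseline detector: a first amplitude
# threshold on the squared whitened samples, calibrated from the estimated
# background-noise variance at a configured false-alarm probability, plus a
# second criterion on the number of supra-threshold samples within a short
# observation window.

#' Configuration of the double-threshold detector
#'
#' @param m Observation-window length in samples.
#' @param r0 Minimum number of supra-threshold auxiliary samples within `m`
#'   for a detection.
#' @param false_alarm_prob Per-window false-alarm probability used to set
#'   the first threshold (mode `"false_alarm_prob"`).
#' @param k_sigma First threshold as a multiple of the noise standard
#'   deviation on the squared samples (mode `"k_sigma"`).
#' @param first_threshold_mode `"false_alarm_prob"` (default) or
#'   `"k_sigma"`.
#' @param noise_quantile Fraction of lowest-energy RMS samples used to
#'   estimate the noise variance when none is supplied.
#' @param min_duration_ms Minimum plausible activation duration; shorter
#'   detections are discarded (run cleaning).
#' @return Object of class `dt_config`.
#' @export
dt_config <- function(m = 5, r0 = 1, false_alarm_prob = 0.05, k_sigma = 3,
                      first_threshold_mode = c("false_alarm_prob", "k_sigma"),
                      noise_quantile = 0.10, min_duration_ms = 30) {
  first_threshold_mode <- match.arg(first_threshold_mode)
  stopifnot(m >= 1, r0 >= 1, r0 <= m,
            false_alarm_prob > 0, false_alarm_prob < 1,
            noise_quantile > 0, noise_quantile < 1)
  structure(list(m = as.integer(m), r0 = as.integer(r0),
                 false_alarm_prob = false_alarm_prob, k_sigma = k_sigma,
                 first_threshold_mode = first_threshold_mode,
                 noise_quantile = noise_quantile,
                 min_duration_ms = min_duration_ms),
            class = "dt_config")
}

# Per-sample exceedance probability p1 such that the probability of at least
# r0 exceedances among m independent samples equals the window false-alarm
# probability.
dt_sample_false_alarm <- function(pfa, m, r0) {
  if (r0 == 1) return(1 - (1 - pfa)^(1 / m))
  f <- function(p) stats::pbinom(r0 - 1, m, p, lower.tail = FALSE) - pfa
  stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

#' Double-threshold activity detection
#'
#' Whitens the signal by the (estimated or supplied) background-noise
#' variance, squares it, and flags a sample as active when at least `r0` of
#' the `m` auxiliary values in the observation window starting at that
#' sample exceed the first threshold. With mode `"false_alarm_prob"` the
#' threshold is the chi-square(1) quantile that yields the configured
#' per-window false-alarm probability under pure noise. Detected activations
#' shorter than `min_duration_ms` are removed (and equally short silent gaps
#' bridged) by [clean_runs()].
#'
#' @param x Numeric signal.
#' @param fs_hz Sampling frequency, Hz.
#' @param config A [dt_config()].
#' @param noise_var Known background-noise variance; when `NULL` it is
#'   estimated as the mean squared value over the `noise_quantile` fraction
#'   of lowest-RMS samples.
#' @param post_process Apply the minimum-duration run cleaning (default
#'   `TRUE`; disable to inspect the raw threshold crossings).
#' @return Integer 0/1 vector, one value per sample.
#' @export
detect_dt <- function(x, fs_hz = 2000, config = dt_config(),
                      noise_var = NULL, post_process = TRUE) {
  stopifnot(inherits(config, "dt_config"))
  n <- length(x)
  if (n == 0) return(integer(0))
  if (is.null(noise_var)) {
    w <- min(60L, n)
    rms <- rms_profile(x, w)
    q <- stats::quantile(rms, config$noise_quantile, names = FALSE)
    silent <- rms <= q
    if (!any(silent)) stop("no silent segment found to estimate noise; ",
                           "supply noise_var")
    noise_var <- mean(x[silent]^2)
    if (noise_var <= 0) noise_var <- .Machine$double.eps
  }
  aux <- x^2 / noise_var
  zeta <- if (config$first_threshold_mode == "false_alarm_prob") {
    p1 <- dt_sample_false_alarm(config$false_alarm_prob, config$m, config$r0)
    stats::qchisq(1 - p1, df = 1)
  } else {
    config$k_sigma^2
  }
  above <- as.integer(aux > zeta)
  # count of exceedances in the forward window [i, i + m - 1], truncated at
  # the signal end
  cs <- cumsum(c(0L, above))
  hi <- pmin(seq_len(n) + config$m - 1L, n)
  counts <- cs[hi + 1L] - cs[seq_len(n)]
  active <- as.integer(counts >= config$r0)
  if (post_process) {
    min_run <- max(1L, round(fs_hz * config$min_duration_ms / 1000))
    active <- clean_runs(active, min_run)
  }
  active
}
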