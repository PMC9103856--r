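test_that("run cleaning removes short activations and bridges short gaps", {
  # 30-sample activation flanked by long silence vanishes (30 ms rule at 2 kHz)
  x <- c(rep(0L, 500), rep(1L, 30), rep(0L, 500))
  expect_identical(clean_runs(x, 60), rep(0L, length(x)))
  # 100-sample activation survives
  y <- c(rep(0L, 500), rep(1L, 100), rep(0L, 500))
  expect_identical(clean_runs(y, 60), y)
  # short interior gap is bridged into one 220-sample activation
  z <- c(rep(1L, 100), rep(0L, 20), rep(1L, 100))
  expect_identical(clean_runs(z, 60), rep(1L, 220))
  # leading/trailing silence is never converted to activity
  lead <- c(rep(0L, 10), rep(1L, 100))
  expect_identical(clean_runs(lead, 60), lead)
})

test_that("run cleaning matches the brute-force oracle and is idempotent", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(50:500, 1)
    b <- as.integer(runif(n) > 0.5)
    # random run structure with plausible run lengths
    r <- rle(b)
    r$lengths <- sample(1:80, length(r$lengths), replace = TRUE)
    b <- inverse.rle(r)
    got <- clean_runs(b, 60)
    expect_identical(got, oracle_clean_runs(b, 60))
    expect_identical(clean_runs(got, 60), got)
    # no interior run shorter than min_run remains
    rr <- rle(got)
    if (length(rr$lengths) > 2) {
      expect_true(all(rr$lengths[2:(length(rr$lengths) - 1)] >= 60))
    }
  }
})

test_that("event extraction scans transitions with edge conventions", {
  expect_length(extract_events(rep(0L, 100))$onsets, 0)
  expect_length(extract_events(rep(1L, 100))$onsets, 0)
  expect_length(extract_events(rep(1L, 100))$offsets, 0)
  b <- c(rep(0L, 800), rep(1L, 400), rep(0L, 800))
  ev <- extract_events(b, 2000)
  expect_identical(ev$onsets, 801L) # 0-based sample 800
  expect_identical(ev$offsets, 1201L) # 0-based sample 1200
  expect_equal(event_times_ms(ev, "onset"), 400)
  expect_equal(event_times_ms(ev, "offset"), 600)
  # run touching the start yields no onset; touching the end no offset
  lead <- extract_events(c(rep(1L, 100), rep(0L, 100)))
  expect_length(lead$onsets, 0)
  expect_identical(lead$offsets, 101L)
  # random sequences against the transition-scan oracle
  for (s in 1:10) {
    set.seed(200 + s)
    b <- as.integer(runif(300) > 0.5)
    ev <- extract_events(b)
    orc <- oracle_events(b)
    expect_identical(as.integer(ev$onsets), orc$onsets)
    expect_identical(as.integer(ev$offsets), orc$offsets)
  }
})

test_that("cleaned sequences never yield same-kind events closer than min_run", {
  n_multi <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    r <- rle(as.integer(runif(40) > 0.5))
    r$lengths <- sample(10:120, length(r$lengths), replace = TRUE)
    b <- inverse.rle(r)
    ev <- extract_events(clean_runs(b, 60))
    if (length(ev$onsets) > 1) {
      n_multi <- n_multi + 1
      expect_true(all(diff(ev$onsets) >= 60))
    }
    if (length(ev$offsets) > 1) expect_true(all(diff(ev$offsets) >= 60))
  }
  expect_gt(n_multi, 0) # the generator must exercise multi-event sequences
})

ev_list <- function(onsets, offsets, fs = 2000) {
  structure(list(onsets = as.integer(onsets), offsets = as.integer(offsets),
                 fs_hz = fs), class = "event_list")
}

test_that("tolerance matching accepts within 100 ms and rejects beyond", {
  fs <- 2000
  # predicted onset at 500 ms vs truth 450 ms: TP, signed error +50 ms
  m <- match_events(ev_list(1001, integer(0)), ev_list(901, integer(0)))
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$error_ms, 50)
  expect_equal(unname(m$fp[["onset"]] + m$fn[["onset"]]), 0)
  # 150 ms away: FP + FN
  m2 <- match_events(ev_list(1001, integer(0)), ev_list(701, integer(0)))
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(unname(m2$fp[["onset"]]), 1)
  expect_equal(unname(m2$fn[["onset"]]), 1)
  # exactly at tolerance is rejected (strict <)
  m3 <- match_events(ev_list(1 + 200, integer(0)), ev_list(1, integer(0)))
  expect_equal(nrow(m3$pairs), 0)
  # two predictions near one truth: exactly one TP, one FP
  m4 <- match_events(ev_list(c(981, 1001), integer(0)),
                     ev_list(1001, integer(0)))
  expect_equal(nrow(m4$pairs), 1)
  expect_equal(unname(m4$fp[["onset"]]), 1)
  expect_equal(m4$pairs$error_ms, 0)
  # onsets never match offsets
  m5 <- match_events(ev_list(1001, integer(0)), ev_list(integer(0), 1001))
  expect_equal(nrow(m5$pairs), 0)
})

test_that("matching an event list with itself is a perfect match", {
  ev <- ev_list(c(101, 901), c(401, 1401))
  m <- match_events(ev, ev)
  expect_equal(nrow(m$pairs), 4)
  expect_true(all(m$pairs$error_ms == 0))
  expect_true(all(m$fp == 0) && all(m$fn == 0))
})

test_that("matcher equals exhaustive optimal matching, <= 4 events/side", {
  for (s in 1:60) {
    set.seed(400 + s)
    np <- sample(0:4, 1); nt <- sample(0:4, 1)
    pred <- sort(sample(1:2000, np))
    truth <- sort(sample(1:2000, nt))
    m <- match_events(ev_list(pred, integer(0)), ev_list(truth, integer(0)))
    opt <- oracle_optimal_match((pred - 1) / 2, (truth - 1) / 2, 100)
    expect_equal(nrow(m$pairs), opt$n)
    expect_equal(sum(abs(m$pairs$error_ms)), opt$cost, tolerance = 1e-9)
  }
})
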