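test_that("sample metrics match hand-computed confusion matrices", {
  perfect <- sample_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$activity$f1, 100)
  expect_equal(perfect$silent$f1, 100)
  expect_equal(perfect$weighted_f1, 100)

  m <- sample_metrics(c(1, 0, 1, 0), c(1, 1, 0, 0))
  expect_equal(m$accuracy, 50)
  expect_equal(m$activity$precision, 50)
  expect_equal(m$activity$recall, 50)
  expect_equal(m$activity$f1, 50)

  allneg <- sample_metrics(c(0, 0, 0, 0), c(1, 0, 1, 0))
  expect_equal(allneg$activity$recall, 0)
  expect_error(sample_metrics(c(1, 0), c(1, 0, 1)), "length")
})

test_that("sample metrics agree with the brute-force oracle to 1e-12", {
  for (s in 1:15) {
    set.seed(500 + s)
    n <- sample(20:500, 1)
    truth <- as.integer(runif(n) > 0.4)
    pred <- truth
    flip <- runif(n) < 0.2
    pred[flip] <- 1L - pred[flip]
    got <- sample_metrics(pred, truth)
    orc <- oracle_sample_metrics(pred, truth)
    expect_equal(got$accuracy, orc$accuracy, tolerance = 1e-12)
    expect_equal(c(got$activity$precision, got$activity$recall,
                   got$activity$f1), orc$activity, tolerance = 1e-12)
    expect_equal(c(got$silent$precision, got$silent$recall, got$silent$f1),
                 orc$silent, tolerance = 1e-12)
    expect_equal(got$macro_f1, orc$macro_f1, tolerance = 1e-12)
    expect_equal(got$weighted_f1, orc$weighted_f1, tolerance = 1e-12)
    # weighted F1 lies between the class F1s
    expect_gte(got$weighted_f1, min(got$activity$f1, got$silent$f1) - 1e-12)
    expect_lte(got$weighted_f1, max(got$activity$f1, got$silent$f1) + 1e-12)
  }
})

ev_list <- function(onsets, offsets, fs = 2000) {
  structure(list(onsets = as.integer(onsets), offsets = as.integer(offsets),
                 fs_hz = fs), class = "event_list")
}

test_that("event metrics follow the precision/recall/F1 formulas", {
  # all truth events matched, no FP
  truth <- ev_list(seq(101, 2000, by = 200), integer(0))
  m <- match_events(truth, truth)
  em <- event_metrics(m)
  expect_equal(em$onset$precision, 100)
  expect_equal(em$onset$recall, 100)
  expect_equal(em$onset$f1, 100)
  # 1 TP + 1 FP, 0 FN
  m2 <- match_events(ev_list(c(201, 1601), integer(0)), ev_list(201,
                                                                integer(0)))
  em2 <- event_metrics(m2)
  expect_equal(em2$onset$precision, 50)
  expect_equal(em2$onset$recall, 100)
  expect_equal(em2$onset$f1, 200 / 3, tolerance = 1e-9)
  # empty vs empty: 100% by convention
  m3 <- match_events(ev_list(integer(0), integer(0)),
                     ev_list(integer(0), integer(0)))
  em3 <- event_metrics(m3)
  expect_equal(em3$onset$f1, 100)
  # empty prediction against existing truth: 0%
  m4 <- match_events(ev_list(integer(0), integer(0)),
                     ev_list(501, integer(0)))
  expect_equal(event_metrics(m4)$onset$recall, 0)
})

test_that("MAE and bias summarize matched-pair timing errors", {
  m <- match_events(ev_list(c(221, 581), integer(0)),
                    ev_list(c(201, 601), integer(0)))
  # errors: +10 ms and -10 ms
  expect_equal(sort(m$pairs$error_ms), c(-10, 10))
  expect_equal(event_mae(m, "onset"), 10)
  expect_equal(event_bias(m, "onset"), 0)
  single <- match_events(ev_list(207, integer(0)), ev_list(201, integer(0)))
  expect_equal(event_mae(single, "onset"), 3)
  expect_equal(event_bias(single, "onset"), 3)
  none <- match_events(ev_list(integer(0), integer(0)),
                       ev_list(501, integer(0)))
  expect_true(is.na(event_mae(none, "onset")))
  expect_true(is.na(event_bias(none, "onset")))
  # |bias| <= MAE on random matchings
  for (s in 1:10) {
    set.seed(600 + s)
    p <- sort(sample(1:1900, 4)); tr <- p + sample(-150:150, 4)
    mm <- match_events(ev_list(p, integer(0)),
                       ev_list(pmax(tr, 1), integer(0)))
    if (nrow(mm$pairs) > 0) {
      expect_lte(abs(event_bias(mm, "onset")), event_mae(mm, "onset") + 1e-12)
    }
  }
})

test_that("stratified report aggregates per-signal metrics correctly", {
  manifest <- data.frame(id = 1:6,
                         sigma_s = rep(c(0.05, 0.1), 3),
                         alpha = rep(1, 6),
                         snr_db = rep(c(3, 10, 30), each = 2),
                         mu_s = 0.5, seed = 1:6)
  results <- data.frame(id = 1:6, accuracy = c(90, 92, 94, 96, 98, 100))
  rep1 <- stratified_report(results, manifest)
  expect_equal(rep1$by_snr$accuracy_mean,
               c(91, 95, 99)[order(c(3, 10, 30))])
  # single-signal stratum: mean equals the value, SD 0
  r1 <- stratified_report(results[1, , drop = FALSE], manifest)
  expect_equal(r1$by_snr$accuracy_mean, 90)
  expect_equal(r1$by_snr$accuracy_sd, 0)
  # permutation invariance
  perm <- results[sample.int(6), ]
  rep2 <- stratified_report(perm, manifest)
  expect_equal(rep2$by_snr, rep1$by_snr)
  # pooled mean equals support-weighted mean of strata
  w <- table(manifest$snr_db)[as.character(rep1$by_snr$snr_db)]
  expect_equal(rep1$pooled$accuracy_mean,
               sum(rep1$by_snr$accuracy_mean * as.numeric(w)) / sum(w))
  expect_error(stratified_report(data.frame(id = 99, accuracy = 1), manifest),
               "manifest")
})
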