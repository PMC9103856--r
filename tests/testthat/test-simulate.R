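test_that("truncated envelope has the stated support, peak and symmetry", {
  p <- sim_params(sigma_s = 0.05, alpha = 1, snr_db = 10, mu_s = 0.5)
  env <- truncated_gaussian_envelope(p)
  expect_length(env, 2000)
  # support = 2 * alpha * sigma = 200 ms ~ 400 samples (+1 for closed ends)
  expect_lte(abs(sum(env > 0) - round(2 * 1 * 0.05 * 2000)), 1)
  # peak 1 at the sample nearest mu
  expect_equal(max(env), 1, tolerance = 1e-4)
  expect_equal(which.max(env), 1001)
  # symmetry about mu for a wider truncation
  p2 <- sim_params(0.05, 2.4, 10, mu_s = 0.5)
  e2 <- truncated_gaussian_envelope(p2)
  ctr <- 1001
  for (k in c(1, 50, 150, 239)) {
    expect_equal(e2[ctr - k], e2[ctr + k], tolerance = 1e-12)
  }
})

test_that("envelope support beyond the window errors unless clipping is enabled", {
  p <- sim_params(0.15, 2.4, 10, mu_s = 0.1)
  expect_error(truncated_gaussian_envelope(p), "support")
  p$clip_edges <- TRUE
  env <- truncated_gaussian_envelope(p)
  expect_gt(sum(env > 0), 0)
})

test_that("burst carrier is zero-mean, band-limited to 80-120 Hz, deterministic", {
  b1 <- burst_process(2000, 2000, seed = 5)
  b2 <- burst_process(2000, 2000, seed = 5)
  expect_identical(b1, b2)
  se <- stats::sd(b1) / sqrt(length(b1))
  expect_lt(abs(mean(b1)), 3 * se)
  expect_error(burst_process(100, fs_hz = 200), "240")

  # spectral concentration: averaged periodogram over 50 seeds, long series
  inband <- vapply(1:50, function(s) {
    x <- burst_process(20000, 2000, seed = s)
    sp <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) / length(x) * 2000
    half <- f <= 1000
    sum(sp[half & f >= 80 & f <= 120]) / sum(sp[half])
  }, numeric(1))
  expect_gt(mean(inband), 0.9)
})

test_that("burst scaling hits the target SNR exactly in every convention", {
  p <- sim_params(0.1, 2, snr_db = 10, mu_s = 0.5)
  env <- truncated_gaussian_envelope(p)
  burst <- burst_process(2000, 2000, seed = 9)
  sup <- env > 0
  # default window reference: epoch-wide power of the modulated burst
  g <- scale_burst_to_snr(burst, env, noise_var = 1, snr_db = 10)
  expect_equal(mean(g^2), 10, tolerance = 1e-9)
  # support reference: mean power over the envelope support
  gs <- scale_burst_to_snr(burst, env, 1, 10, power_ref = "support")
  expect_equal(mean(gs[sup]^2), 10, tolerance = 1e-9)
  gs0 <- scale_burst_to_snr(burst, env, 2, 0, power_ref = "support")
  expect_equal(mean(gs0[sup]^2) / 2, 1, tolerance = 1e-9)
  gs30 <- scale_burst_to_snr(burst, env, 1, 30, power_ref = "support")
  expect_equal(mean(gs30[sup]^2), 1000, tolerance = 1e-6)
  # window reference boosts support-local power by 1/support_fraction
  expect_equal(mean(g[sup]^2), 10 / mean(sup), tolerance = 1e-9)
  expect_error(scale_burst_to_snr(burst, numeric(2000), 1, 10), "support")
})

test_that("simulated signal has stated length, ground truth and determinism", {
  p <- sim_params(0.1, 2, snr_db = 60, seed = 21)
  s1 <- simulate_semg(p)
  s2 <- simulate_semg(p)
  expect_identical(s1$samples, s2$samples)
  expect_length(s1$samples, 2000)
  expect_identical(s1$ground_truth, as.integer(s1$envelope > 0))
  # exactly one activation run
  r <- rle(s1$ground_truth)
  expect_equal(sum(r$values == 1L), 1)
  # at 60 dB noise is negligible: support power dwarfs outside power
  sup <- s1$ground_truth == 1
  expect_gt(mean(s1$samples[sup]^2) / mean(s1$samples[!sup]^2), 100)
})

test_that("ground-truth run length matches 2*alpha*sigma*fs across the grid", {
  for (sg in c(0.05, 0.10, 0.15)) {
    for (al in c(1, 1.5, 2, 2.4)) {
      if (2 * al * sg >= 1) next
      s <- simulate_semg(sim_params(sg, al, 10, seed = round(1e4 * sg * al)))
      expect_lte(abs(sum(s$ground_truth) - round(2 * al * sg * 2000)), 1)
    }
  }
})

test_that("empirical SNR recovers the target within 1 dB on average", {
  for (snr in c(10, 20)) {
    # support reference: support/outside variance ratio is the target
    vals_sup <- vapply(1:50, function(i) {
      s <- simulate_semg(sim_params(0.1, 2, snr, seed = 1000 * snr + i,
                                    snr_ref = "support"))
      sup <- s$ground_truth == 1
      10 * log10(mean(s$samples[sup]^2) / mean(s$samples[!sup]^2))
    }, numeric(1))
    expect_lt(abs(mean(vals_sup) - snr), 1)
    # window reference (default): excess epoch variance over the noise
    # variance is the target
    vals_win <- vapply(1:50, function(i) {
      s <- simulate_semg(sim_params(0.1, 2, snr, seed = 3000 * snr + i))
      10 * log10((mean(s$samples^2) - 1) / 1)
    }, numeric(1))
    expect_lt(abs(mean(vals_win) - snr), 1)
  }
})

test_that("disjoint seeds give uncorrelated signals", {
  # noise-dominated regime: ~2000 effective degrees of freedom, so the
  # lag-0 correlation of independent realizations is tightly bounded
  a <- simulate_semg(sim_params(0.1, 2, -20, mu_s = 0.5, seed = 1))
  b <- simulate_semg(sim_params(0.1, 2, -20, mu_s = 0.5, seed = 2))
  expect_lt(abs(stats::cor(a$samples, b$samples)), 0.1)
  # burst-dominated signals are narrowband (~32 effective dof at lag 0);
  # independence shows in the pair-averaged correlation instead
  r <- vapply(1:10, function(k) {
    x <- simulate_semg(sim_params(0.1, 2, 10, mu_s = 0.5, seed = 2 * k))
    y <- simulate_semg(sim_params(0.1, 2, 10, mu_s = 0.5, seed = 2 * k + 1))
    stats::cor(x$samples, y$samples)
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.1)
})

test_that("dataset generation respects grid sizes and seed bookkeeping", {
  expect_error(generate_dataset(dataset_spec(numeric(0), 1, 1)), ".")
  d1 <- generate_dataset(dataset_spec(0.05, 1, 10, reps = 1, seed = 1))
  expect_length(d1$signals, 1)
  # default grids multiply out to the documented sizes
  tg <- training_grid()
  expect_equal(length(tg$sigmas_s) * length(tg$alphas) * length(tg$snrs_db) *
                 tg$reps, 2880)
  eg <- test_grid()
  expect_equal(length(eg$sigmas_s) * length(eg$alphas) * length(eg$snrs_db) *
                 eg$reps, 864)
  # different base seeds share no per-signal seed
  da <- generate_dataset(dataset_spec(0.05, c(1, 2), c(5, 10), reps = 2,
                                      seed = 1))
  db <- generate_dataset(dataset_spec(0.05, c(1, 2), c(5, 10), reps = 2,
                                      seed = 2))
  expect_length(intersect(da$manifest$seed, db$manifest$seed), 0)
  # manifest matches the generating parameters
  i <- 5
  expect_equal(da$signals[[i]]$params$snr_db, da$manifest$snr_db[i])
  expect_equal(da$signals[[i]]$params$mu_s, da$manifest$mu_s[i])
})
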