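gamma30 <- decay_factor(30)

test_that("robust noise floor: calibration, shift invariance, homogeneity", {
  set.seed(5)
  x <- rnorm(1e5, 0, 0.05)
  s <- robust_noise_std(x, 30)
  expect_lt(abs(s - 0.05), 0.002)
  expect_equal(robust_noise_std(x + 10, 30), s)
  expect_equal(robust_noise_std(2 * x, 30), 2 * s)
  expect_equal(robust_noise_std(rep(3, 500), 30), 0)
  expect_error(robust_noise_std(rnorm(50), 30), class = "calspike_short_trace")
})

test_that("exact L0 solver matches enumeration and recovers clean transients", {
  # flat trace
  ev <- l0_exact_events(rep(0, 50), gamma30, lam = 0.01)
  expect_length(ev$event_frames, 0)

  # clean geometric transient: one event, exact amplitude
  y <- c(rep(0, 4), gamma30^(0:15))
  ev <- l0_exact_events(y, gamma30, lam = 1e-4)
  expect_equal(ev$event_frames, 5L)
  expect_equal(ev$amplitudes, 1, tolerance = 1e-9)

  # penalty-dominated limit: no events, single geometric trajectory
  ev_inf <- l0_exact_events(y, gamma30, lam = 1e6)
  expect_length(ev_inf$event_frames, 0)
  expect_length(attr(ev_inf, "changepoints"), 1)

  expect_error(l0_exact_events(c(1, NA, 0), gamma30, lam = 0.1),
               class = "calspike_bad_trace")

  # exactness vs exhaustive enumeration, and amplitude positivity
  set.seed(11)
  for (i in 1:20) {
    T <- sample(6:12, 1)
    y <- rnorm(T, 0, 0.05)
    if (i %% 2 == 0) y[3] <- y[3] + 0.4
    lam <- sample(c(5e-4, 2e-3, 1e-2), 1)
    ev <- l0_exact_events(y, gamma30, lam)
    expect_equal(attr(ev, "cost"), brute_force_l0(y, gamma30, lam),
                 tolerance = 1e-10)
    if (length(ev$amplitudes)) expect_true(all(ev$amplitudes > 0))
  }
})

test_that("noise-calibrated extraction honours the 200% noise-floor contract", {
  # constraint already satisfied (huge transient, tiny noise): calibrated
  # result is the uncalibrated lambda0 extraction
  set.seed(199)
  y <- c(rep(0, 120), 0.8 * gamma30^(0:100), rep(0, 40)) + rnorm(261, 0, 0.003)
  cal <- calibrate_and_extract(y)
  expect_equal(cal$lambda, cal$sigma^2 * log(length(y)), tolerance = 1e-12)
  expect_equal(length(cal$events$event_frames), 1)

  # seeded synthetic traces: smallest event >= 2 sigma; lambda* also keeps
  # the min amplitude above what any smaller lambda would give
  for (s in 1:3) {
    set.seed(200 + s)
    st <- cumsum(rexp(600, 5)); st <- st[st < 60]
    tr <- spikes_to_fluorescence(st, 60, seed = s)
    cal <- calibrate_and_extract(tr)
    expect_gt(length(cal$events$amplitudes), 0)
    expect_gte(min(cal$events$amplitudes), 2 * cal$sigma - 1e-12)
    # min-amplitude monotonicity across a lambda grid
    lams <- cal$lambda * c(0.25, 0.5, 1)
    minamps <- vapply(lams, function(l) {
      ev <- l0_exact_events(tr, lam = l)
      if (length(ev$amplitudes)) min(ev$amplitudes) else Inf
    }, numeric(1))
    expect_true(all(diff(minamps) >= -1e-9))
  }
})

test_that("NND matches a generic constrained solver and scales amplitudes", {
  expect_length(nnd_events(rep(0, 400))$event_frames, 0)

  # kernel-matched transient at 30 Hz: events concentrate at onset and the
  # summed amplitude recovers the true jump within 10%
  y <- c(rep(0, 30), 0.5 * gamma30^(0:120), rep(0, 30))
  ev <- nnd_events(y)
  expect_gt(length(ev$event_frames), 0)
  tt <- event_times(ev)
  onset <- abs(tt - 1.0) < 0.15
  expect_gt(sum(ev$amplitudes[onset]) / sum(ev$amplitudes), 0.9)
  expect_lt(abs(sum(ev$amplitudes) - 0.5) / 0.5, 0.1)

  # dual route: our pooled solution attains the oracle NNLS objective on
  # the already-upsampled instance
  set.seed(41)
  g150 <- decay_factor(150)
  s_true <- 0.3 * tabulate(c(40, 90), 300)
  y150 <- as.numeric(stats::filter(s_true, g150, method = "recursive")) +
    rnorm(300, 0, 0.01)
  c_fit <- calspike:::oasis_nnd_cpp(y150, g150)
  s_fit <- c_fit - g150 * c(0, head(c_fit, -1))
  obj_ours <- 0.5 * sum((y150 - c_fit)^2)
  oracle <- nnls_oracle(y150, g150)
  expect_lt(obj_ours, oracle$objective + 1e-6)
  expect_true(all(s_fit > -1e-9))

  # with noise, unpenalized NND yields far more events than calibrated L0
  set.seed(42)
  st <- cumsum(rexp(300, 3)); st <- st[st < 60]
  tr <- spikes_to_fluorescence(st, 60, seed = 7)
  n_nnd <- length(nnd_events(tr)$event_frames)
  n_l0 <- length(calibrate_and_extract(tr)$events$event_frames)
  expect_gt(n_nnd, 3 * n_l0)
})

test_that("binned amplitude thresholding is all-or-none per bin", {
  sigma <- 0.05
  # three bins with summed magnitudes 1, 3, 5 noise SDs
  ev <- event_series(c(1, 4, 7), c(1, 3, 5) * sigma, frame_rate_hz = 30)
  expect_identical(threshold_binned_events(ev, k = 0, sigma = sigma), ev)
  expect_length(threshold_binned_events(ev, k = Inf, sigma = sigma)$event_frames, 0)
  kept <- threshold_binned_events(ev, k = 4, sigma = sigma)
  expect_equal(kept$amplitudes, 5 * sigma)
  # splitting a bin's magnitude across two events keeps/drops them together
  ev2 <- event_series(c(1, 2), c(2.5, 2.5) * sigma, frame_rate_hz = 30)
  expect_length(threshold_binned_events(ev2, k = 4, sigma = sigma)$amplitudes, 2)
})

test_that("ground-truth benchmarking classifies bins and degrades gracefully", {
  # events exactly at spike bins: no misses, no false positives
  # (spike times chosen away from bin edges)
  spikes <- c(0.05, 1.25, 3.37)
  ev <- event_series(floor(spikes * 30) + 1, rep(0.1, 3), frame_rate_hz = 30)
  b <- benchmark_against_ground_truth(ev, spikes, bin_s = 0.1, duration_s = 5)
  expect_equal(b$miss, 0)
  expect_equal(b$false_positive, 0)
  expect_equal(b$hit, 3)
  expect_equal(b$hit + b$miss + b$false_positive + b$correct_reject, b$n_bins)

  # no events: correlation reported as 0 with a flag, FP rate 0
  b0 <- benchmark_against_ground_truth(event_series(frame_rate_hz = 30),
                                       spikes, 0.1, 5)
  expect_false(b0$correlation_defined)
  expect_equal(b0$rate_correlation, 0)
  expect_equal(b0$fp_rate, 0)
})
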