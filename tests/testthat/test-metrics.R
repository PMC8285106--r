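mini_table <- function(starts, stops, cond = "c1", type = "drifting_gratings") {
  data.frame(trial_id = seq_along(starts), stimulus_type = type,
             start_s = starts, stop_s = stops, condition_id = cond)
}

test_that("trial magnitudes: counting, summation, half-open boundaries", {
  tbl <- mini_table(1, 3)
  expect_equal(trial_response_magnitudes(c(1.1, 1.5), tbl)$magnitude, 2)
  ev <- event_series(c(34, 46), c(0.02, 0.07), frame_rate_hz = 30)
  expect_equal(trial_response_magnitudes(ev, tbl)$magnitude, 0.09)
  expect_equal(trial_response_magnitudes(ev, tbl)$modality, "imaging")

  # spike exactly at stop is excluded; exactly at start is included
  expect_equal(trial_response_magnitudes(c(3), tbl)$magnitude, 0)
  expect_equal(trial_response_magnitudes(c(1), tbl)$magnitude, 1)

  expect_warning(trial_response_magnitudes(c(0.5), mini_table(10, 12)),
                 "outside the activity time range")
})

test_that("response reliability implements the strict 95% counting rule", {
  sp <- c(start_s = 100, stop_s = 400)
  trials <- mini_table(seq(0, 28, 2), seq(0, 28, 2) + 2)  # 15 trials of 2 s

  # every trial beats the (empty) null activity
  act <- sort(c(outer(trials$start_s, c(0.1, 0.2, 0.3), `+`)))
  r <- response_reliability(act, trials, sp, n_draws = 500, seed = 1)
  expect_equal(r$reliability, 100)
  expect_true(r$responsive)

  # silent unit: strict inequality fails on all-zero magnitudes
  r0 <- response_reliability(numeric(0), trials, sp, n_draws = 500, seed = 1)
  expect_equal(r0$reliability, 0)
  expect_false(r0$responsive)

  # 5 of 15 trials above the null's 95th percentile: 33.3%, responsive at
  # 25 but not at 40
  act5 <- sort(c(outer(trials$start_s[1:5], c(0.1, 0.2, 0.3), `+`)))
  r5 <- response_reliability(act5, trials, sp, n_draws = 500, seed = 1)
  expect_equal(r5$reliability, 100 * 5 / 15, tolerance = 1e-9)
  expect_true(r5$responsive)
  r5b <- response_reliability(act5, trials, sp, n_draws = 500, seed = 1,
                              threshold = 40)
  expect_false(r5b$responsive)

  expect_error(response_reliability(act, trials[0, ], sp),
               class = "calspike_no_trials")
  expect_error(response_reliability(act, trials, c(0, 1)),
               class = "calspike_short_spontaneous")
})

test_that("lifetime sparseness matches the closed form and its invariances", {
  expect_equal(lifetime_sparseness(c(1, 0, 0, 0)), 1)
  expect_equal(lifetime_sparseness(rep(0.37, 8)), 0)
  expect_equal(lifetime_sparseness(c(2, 1, 1, 0)), 4 / 9)
  expect_true(is.na(lifetime_sparseness(c(0, 0, 0))))
  expect_error(lifetime_sparseness(c(1, -1)),
               class = "calspike_negative_response")
  set.seed(8)
  for (i in 1:25) {
    r <- rexp(sample(2:40, 1))
    s <- lifetime_sparseness(r)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(lifetime_sparseness(3.7 * r), s, tolerance = 1e-12)
  }
})

test_that("gOSI and preference follow the stated conventions", {
  expect_equal(gOSI(c(1, 0, 0, 0, 0, 0, 0, 0)), 1)
  expect_equal(gOSI(rep(2, 8)), 0, tolerance = 1e-12)
  expect_equal(gOSI(c(2, 0, 1, 0, 0, 0, 0, 0)), 1 / 3, tolerance = 1e-12)
  expect_true(is.na(gOSI(rep(0, 8))))

  # marginal temporal-frequency preference, with the lowest-index tie rule
  tfs <- c(1, 2, 4, 8, 15)
  means <- c(0.1, 0.5, 0.4, 0.2, 0.1)
  tbl <- do.call(rbind, lapply(seq_along(tfs), function(i) {
    d <- mini_table(10 * i + c(0, 3), 10 * i + c(2, 5),
                    cond = sprintf("dg_tf%02d", tfs[i]))
    d$temporal_frequency_hz <- tfs[i]
    d
  }))
  tbl$trial_id <- seq_len(nrow(tbl))
  rt <- data.frame(trial_id = tbl$trial_id, condition_id = tbl$condition_id,
                   stimulus_type = "drifting_gratings",
                   magnitude = rep(means, each = 2), modality = "ephys")
  pm <- preference_metrics(rt, tbl)
  expect_equal(pm$preferred_temporal_frequency_hz, 2)

  rt$magnitude <- rep(c(0.1, 0.5, 0.5, 0.2, 0.1), each = 2)  # tie 2 vs 4 Hz
  expect_equal(preference_metrics(rt, tbl)$preferred_temporal_frequency_hz, 2)
})

test_that("identical magnitudes give identical metrics across modalities", {
  # drifting gratings + spontaneous session with exactly representable
  # trial boundaries (multiples of 3 s), so frame quantization cannot move
  # activity across a boundary
  dg <- make_stimulus_table("drifting_gratings", repeats = 3, seed = 12)
  sp <- make_stimulus_table("spontaneous", start_s = max(dg$stop_s) + 1,
                            spontaneous_duration_s = 120)
  ses <- rbind(cbind(dg, image_id = NA, frame_id = NA,
                     orientation_deg = NA, phase = NA),
               cbind(sp[, c("trial_id", "stimulus_type", "start_s", "stop_s",
                            "condition_id")],
                     direction_deg = NA, temporal_frequency_hz = NA,
                     spatial_frequency_cpd = NA, image_id = NA, frame_id = NA,
                     orientation_deg = NA, phase = NA))
  ses$trial_id <- seq_len(nrow(ses))

  set.seed(13)
  raw <- sort(runif(800, 0, max(ses$stop_s)))
  frames <- sort(unique(floor(raw * 30) + 1))
  st <- (frames - 1) / 30  # one spike per occupied frame, at the frame time
  ev <- event_series(frames, rep(1, length(frames)), frame_rate_hz = 30)
  m_spk <- unit_metrics(st, ses, n_draws = 400, seed = 5)
  m_ev <- unit_metrics(ev, ses, n_draws = 400, seed = 5)
  num <- c("response_reliability", "lifetime_sparseness_raw", "gOSI")
  for (cc in num) expect_equal(m_ev[[cc]], m_spk[[cc]], tolerance = 1e-9)
  expect_identical(m_ev$responsive, m_spk$responsive)
})
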