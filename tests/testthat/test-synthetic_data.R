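test_that("stimulus tables implement the standard condition grids", {
  dg <- make_stimulus_table("drifting_gratings", repeats = 15, seed = 7)
  expect_equal(nrow(dg), 600)
  expect_equal(length(unique(dg$condition_id)), 40)  # 8 directions x 5 TFs
  expect_setequal(unique(dg$direction_deg), seq(0, 315, 45))
  expect_setequal(unique(dg$temporal_frequency_hz), c(1, 2, 4, 8, 15))
  expect_true(all(abs(dg$stop_s - dg$start_s - 2) < 1e-12))

  sg <- make_stimulus_table("static_gratings", repeats = 2, seed = 7)
  expect_equal(length(unique(sg$condition_id)), 5 * 6 * 4)
  expect_true(all(abs(sg$stop_s - sg$start_s - 0.25) < 1e-12))

  ns <- make_stimulus_table("natural_scenes", repeats = 1, seed = 7)
  expect_equal(length(unique(ns$image_id)), 118)

  nm <- make_stimulus_table("natural_movie", repeats = 2, clip_duration_s = 5)
  expect_equal(nrow(nm), 2 * 150)
  expect_true(all(abs(nm$stop_s - nm$start_s - 1 / 30) < 1e-12))

  expect_error(make_stimulus_table("drifting_gratings", repeats = 0),
               class = "calspike_bad_repeats")
  expect_error(make_stimulus_table("flashes"),
               class = "calspike_bad_stimulus_type")
})

test_that("sessions partition time with ordered non-overlapping trials", {
  ses <- quick_session(seed = 3)
  expect_true(all(diff(ses$start_s) > -1e-12))
  expect_true(all(ses$start_s[-1] - ses$stop_s[-nrow(ses)] > -1e-9))
  expect_equal(sum(ses$stimulus_type == "spontaneous"), 1)
  # seeded order is reproducible, and a different seed permutes trials
  ses2 <- quick_session(seed = 3)
  expect_identical(ses, ses2)
  ses3 <- quick_session(seed = 4)
  expect_false(identical(ses$condition_id, ses3$condition_id))
})

test_that("population simulation is seed-reproducible and rate-faithful", {
  ses <- quick_session(seed = 1, spont_s = 300)
  spec <- population_spec(n_units = 3, seed = 5)
  pop_a <- simulate_population(spec, ses)
  pop_b <- simulate_population(spec, ses)
  expect_identical(lapply(pop_a$units, `[[`, "spike_times"),
                   lapply(pop_b$units, `[[`, "spike_times"))
  for (u in pop_a$units) {
    expect_true(all(diff(u$spike_times) > 0))
  }

  # a 1 Hz baseline over a 300 s spontaneous epoch gives 300 +/- 2*sqrt(300)
  sp <- ses[ses$stimulus_type == "spontaneous", ]
  spec1 <- population_spec(n_units = 1, rate_meanlog = log(1), rate_sdlog = 0,
                           evoked_gain_meanlog = 0, evoked_gain_sdlog = 0,
                           burst_propensity = 0, p_responsive = 0)
  counts <- vapply(1:8, function(s) {
    u <- simulate_population(spec1, ses, seed = s)$units[[1]]
    sum(u$spike_times >= sp$start_s & u$spike_times < sp$stop_s)
  }, numeric(1))
  expect_true(all(abs(counts - 300) <= 2 * sqrt(300) + 1e-9))

  # untuned unit: per-condition drifting-grating counts are flat
  u <- simulate_population(spec1, ses, seed = 11)$units[[1]]
  dg <- ses[ses$stimulus_type == "drifting_gratings", ]
  rt <- trial_response_magnitudes(u$spike_times, dg)
  tab <- tapply(rt$magnitude, rt$condition_id, sum)
  chi <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(chi$p.value, 0.01)
})

test_that("missing stimulus coverage is rejected", {
  ses <- quick_session(seed = 1)
  no_spont <- ses[ses$stimulus_type != "spontaneous", ]
  expect_error(simulate_population(population_spec(n_units = 1), no_spont),
               class = "calspike_no_spontaneous")
  no_nm <- ses[ses$stimulus_type != "natural_movie", ]
  expect_error(simulate_population(population_spec(n_units = 1), no_nm),
               class = "calspike_incomplete_session")
})

test_that("forced bursts put >=3 sub-10 ms ISIs in every preferred trial", {
  ses <- quick_session(seed = 2)
  spec <- population_spec(n_units = 1, burst_propensity = 1, burst_size = 4,
                          p_responsive = 1, rate_sdlog = 0)
  u <- simulate_population(spec, ses, seed = 9)$units[[1]]
  dg <- ses[ses$stimulus_type == "drifting_gratings", ]
  pref <- dg[dg$direction_deg == u$tuning$pref_direction_deg &
               dg$temporal_frequency_hz == u$tuning$pref_tf_hz, ]
  expect_gt(nrow(pref), 0)
  for (i in seq_len(nrow(pref))) {
    st <- u$spike_times[u$spike_times >= pref$start_s[i] &
                          u$spike_times < pref$stop_s[i]]
    expect_gte(sum(diff(st) < 0.010), 3)
  }
})

test_that("contamination injection merges the stated fraction and raises ISI violations", {
  set.seed(21)
  a <- fake_unit(1, sort(runif(500, 0, 100)), 100)
  b <- fake_unit(2, sort(runif(400, 0, 100)), 100)
  expect_identical(inject_contamination(a, b, 0)$spike_times, a$spike_times)
  full <- inject_contamination(a, b, 1)
  expect_equal(length(full$spike_times),
               length(unique(c(a$spike_times, b$spike_times))))
  expect_equal(full$contamination_fraction_truth, 1)
  expect_error(inject_contamination(a, a, 0.5), class = "calspike_self_donor")

  # monotonicity of the ISI violations score in injected fraction,
  # averaged over a seed ensemble (same per-seed donor stream gives nested
  # injected subsets, so the trend is clean up to count noise)
  fractions <- seq(0, 0.5, by = 0.1)
  mean_scores <- vapply(fractions, function(fr) {
    mean(vapply(1:10, function(s) {
      set.seed(1000 + s)
      t1 <- fake_unit(1, refractory_poisson(10, 300), 300)
      t2 <- fake_unit(2, refractory_poisson(10, 300), 300)
      as.numeric(isi_violations_score(
        inject_contamination(t1, t2, fr, seed = s)$spike_times, 300))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_scores) >= -0.02 * max(mean_scores)))
  expect_gt(mean_scores[6], 5 * max(mean_scores[1], 1e-6))
})

test_that("selection bias drops low-rate units as specified", {
  set.seed(31)
  rates <- rlnorm(1000, log(2), 1)
  units <- lapply(seq_along(rates), function(i) {
    n <- max(1, rpois(1, rates[i] * 10))
    fake_unit(i, sort(runif(n, 0, 10)), 10)
  })
  emp_rates <- vapply(units, function(u) length(u$spike_times) / 10, numeric(1))

  # hard threshold keeps exactly the units at/above threshold
  thr <- median(emp_rates)
  kept <- apply_selection_bias(units, thr, Inf, seed = 2)
  kept_rates <- vapply(kept, function(u) length(u$spike_times) / 10, numeric(1))
  expect_true(all(kept_rates >= thr))
  expect_equal(length(kept), sum(emp_rates >= thr))
  # ~50% retained at the median (binomial slack)
  expect_lt(abs(length(kept) / 1000 - 0.5), 0.06)

  # threshold 0 keeps everything
  expect_equal(length(apply_selection_bias(units, 0, Inf)), 1000)

  # soft selection shifts the retained rate distribution upward
  soft <- apply_selection_bias(units, thr, 2, seed = 3)
  soft_rates <- vapply(soft, function(u) length(u$spike_times) / 10, numeric(1))
  grid <- quantile(emp_rates, c(0.25, 0.5, 0.75))
  ecdf_all <- stats::ecdf(emp_rates)(grid)
  ecdf_kept <- stats::ecdf(soft_rates)(grid)
  expect_true(all(ecdf_kept <= ecdf_all + 1e-12))
})
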