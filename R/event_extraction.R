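#' Event extraction configuration
#'
#' Conventions shared by the two event extractors: the transient decay
#' half-time is fixed at 315 ms; the sparsity of the L0 extractor is
#' calibrated so the smallest detected event is at least 200% of the trace's
#' robust noise floor; non-negative deconvolution runs on traces upsampled
#' 30 to 150 Hz; benchmarking uses 100 ms (and optionally 250 ms) bins and
#' integer noise-multiple thresholds k = 0..10.
#'
#' @param half_time_s transient decay half-time (s).
#' @param min_event_noise_multiple smallest-event / noise-floor ratio
#'   enforced by calibration.
#' @param lambda_rel_tol relative tolerance of the lambda bisection.
#' @param lambda_max_iter cap on calibration iterations.
#' @param nnd_upsample_factor upsampling factor for NND (30 -> 150 Hz).
#' @param benchmark_bin_s candidate benchmarking bin widths (s).
#' @param threshold_grid integer noise multiples for post-hoc thresholding.
#' @return an object of class `extraction_config`.
#' @export
extraction_config <- function(half_time_s = 0.315,
                              min_event_noise_multiple = 2,
                              lambda_rel_tol = 1e-2,
                              lambda_max_iter = 60,
                              nnd_upsample_factor = 5,
                              benchmark_bin_s = c(0.1, 0.25),
                              threshold_grid = 0:10) {
  stopifnot(half_time_s > 0, min_event_noise_multiple >= 0)
  structure(as.list(environment()), class = "extraction_config")
}

#' Per-frame decay factor implied by a transient half-time
#'
#' @param frame_rate_hz sampling rate (Hz).
#' @param half_time_s decay half-time (s); 315 ms gives ~0.9293 at 30 Hz.
#' @return the AR(1) decay factor `2^(-1/(frame_rate_hz * half_time_s))`.
#' @export
decay_factor <- function(frame_rate_hz, half_time_s = 0.315) {
  2^(-1 / (frame_rate_hz * half_time_s))
}

#' Event series container
#'
#' @param event_frames strictly increasing 1-based frame indices.
#' @param amplitudes positive event amplitudes (dF/F units).
#' @param frame_rate_hz sampling rate of the source trace.
#' @param source optional source trace identifier.
#' @return an object of class `event_series`.
#' @export
event_series <- function(event_frames = integer(0), amplitudes = numeric(0),
                         frame_rate_hz = 30, source = NULL) {
  stopifnot(length(event_frames) == length(amplitudes))
  if (length(amplitudes) && any(amplitudes <= 0)) {
    abort_calspike("event amplitudes must be positive",
                   "calspike_bad_amplitude")
  }
  if (length(event_frames) > 1 && any(diff(event_frames) <= 0)) {
    abort_calspike("event frames must be strictly increasing",
                   "calspike_bad_frames")
  }
  structure(list(event_frames = as.integer(event_frames),
                 amplitudes = as.numeric(amplitudes),
                 frame_rate_hz = frame_rate_hz, source = source),
            class = "event_series")
}

#' @rdname event_series
#' @param events an `event_series`.
#' @return `event_times`: onset times in seconds (frame start).
#' @export
event_times <- function(events) (events$event_frames - 1) / events$frame_rate_hz

trace_values <- function(trace) {
  if (inherits(trace, "fluorescence_trace")) trace$values else as.numeric(trace)
}

trace_rate <- function(trace, default = 30) {
  if (inherits(trace, "fluorescence_trace")) trace$frame_rate_hz else default
}

#' Robust noise floor of a dF/F trace
#'
#' Median-absolute-deviation estimate of the noise SD of the detrended
#' trace: the trace minus a 1 s running-median version, then
#' `1.4826 * mad`. Invariant to additive constants; scales linearly with
#' the trace.
#'
#' @param trace a `fluorescence_trace` or numeric vector.
#' @param frame_rate_hz sampling rate, used for the 1 s median window.
#' @return the noise SD estimate (dF/F units).
#' @export
robust_noise_std <- function(trace, frame_rate_hz = trace_rate(trace)) {
  v <- trace_values(trace)
  if (length(v) < 100) {
    abort_calspike("trace too short for noise estimation (need >= 100 frames)",
                   "calspike_short_trace")
  }
  if (any(!is.finite(v))) {
    abort_calspike("trace contains non-finite values", "calspike_bad_trace")
  }
  k <- round(frame_rate_hz)
  if (k %% 2 == 0) k <- k + 1
  k <- max(3, min(k, length(v) - (1 - length(v) %% 2)))
  r <- v - runmed(v, k)
  1.4826 * median(abs(r - median(r)))
}

#' Exact L0-penalized changepoint event extraction
#'
#' Computes the exact global minimizer of
#' `0.5 * sum (y_t - c_t)^2 + lambda * #{t : c_t != gamma_decay * c_{t-1}}`
#' over calcium fits that decay geometrically between changepoints (a
#' pruned-DP changepoint formulation). Events are reported at changepoints
#' with positive amplitude `c_t - gamma_decay * c_{t-1}`.
#'
#' @param trace a `fluorescence_trace` or numeric vector.
#' @param gamma_decay per-frame decay in (0, 1); defaults to the 315 ms
#'   half-time at the trace frame rate (~0.9293 at 30 Hz).
#' @param lam L0 penalty (> 0).
#' @return an `event_series` with attributes `cost` (optimal objective),
#'   `fit` (fitted calcium trace), and `changepoints` (all segment starts).
#' @export
l0_exact_events <- function(trace, gamma_decay = NULL, lam) {
  v <- trace_values(trace)
  f <- trace_rate(trace)
  if (is.null(gamma_decay)) gamma_decay <- decay_factor(f)
  stopifnot(gamma_decay > 0, gamma_decay < 1, lam > 0)
  if (any(!is.finite(v))) {
    abort_calspike("trace contains non-finite values", "calspike_bad_trace")
  }
  res <- l0_dp_cpp(v, gamma_decay, lam)
  starts <- res$seg_starts
  fit <- res$fit
  amp <- numeric(0); frames <- integer(0)
  if (length(starts) > 1) {
    cp <- starts[-1]
    a <- fit[cp] - gamma_decay * fit[cp - 1]
    pos <- a > 0
    frames <- cp[pos]; amp <- a[pos]
  }
  ev <- event_series(frames, amp, frame_rate_hz = f)
  attr(ev, "cost") <- res$cost
  attr(ev, "fit") <- fit
  attr(ev, "changepoints") <- starts
  ev
}

#' Noise-calibrated L0 extraction
#'
#' Runs [l0_exact_events()] with the penalty adjusted iteratively so the
#' smallest detected event is at least `min_event_noise_multiple` (default
#' 2, i.e. 200%) times the robust noise floor. Starting from
#' `lambda0 = sigma^2 * log(T)`, lambda is increased geometrically until the
#' constraint holds (an empty series satisfies it vacuously), then bisected
#' down to relative tolerance; if the constraint already holds at `lambda0`
#' the uncalibrated extraction is returned.
#'
#' @param trace a `fluorescence_trace` or numeric vector.
#' @param config an [extraction_config()].
#' @return a list with `events` (an `event_series`), `lambda`, and `sigma`
#'   (the noise floor estimate).
#' @export
calibrate_and_extract <- function(trace, config = extraction_config()) {
  v <- trace_values(trace)
  f <- trace_rate(trace)
  gamma <- decay_factor(f, config$half_time_s)
  sigma <- robust_noise_std(trace, f)
  floor_amp <- config$min_event_noise_multiple * sigma

  lam0 <- max(sigma^2 * log(length(v)), 1e-12)
  run <- function(lam) l0_exact_events(v, gamma, lam)
  ok <- function(ev) {
    length(ev$amplitudes) == 0 || min(ev$amplitudes) >= floor_amp
  }

  ev <- run(lam0)
  if (ok(ev)) {
    return(list(events = ev, lambda = lam0, sigma = sigma))
  }
  # increase lambda until the constraint holds; the smallest surviving
  # amplitude scales like sqrt(2 * lambda * (1 - gamma^2)), so jumping by
  # the squared amplitude ratio lands near the target in a few solves
  lo <- lam0       # fails the constraint
  hi <- lam0
  ev_hi <- ev
  for (i in seq_len(config$lambda_max_iter)) {
    ratio <- (floor_amp / min(ev_hi$amplitudes))^2
    hi <- hi * min(max(ratio, 2), 16)
    ev_hi <- run(hi)
    if (ok(ev_hi)) break
    lo <- hi
  }
  # bisect to the smallest lambda satisfying the constraint
  while ((hi - lo) / hi > config$lambda_rel_tol) {
    mid <- sqrt(lo * hi)
    ev_mid <- run(mid)
    if (ok(ev_mid)) {
      hi <- mid; ev_hi <- ev_mid
    } else {
      lo <- mid
    }
  }
  list(events = ev_hi, lambda = hi, sigma = sigma)
}

# Polyphase resampling by integer factor `up`: zero-stuffing followed by a
# Hamming-windowed sinc low-pass (cutoff at the original Nyquist), gain
# `up`, group delay removed.
resample_poly <- function(x, up) {
  if (up == 1) return(x)
  n <- length(x)
  half <- 10L * up
  k <- seq(-half, half)
  h <- ifelse(k == 0, 1 / up, sin(pi * k / up) / (pi * k))
  h <- up * h * (0.54 + 0.46 * cos(pi * k / half))  # Hamming-windowed sinc
  z <- numeric(n * up)
  z[seq(1, by = up, length.out = n)] <- x
  # pad by edge replication (in the stuffed domain) to tame boundary ripple
  pad <- numeric(half)
  zp <- c(pad, z, pad)
  y <- convolve(zp, rev(h), type = "open")
  y <- y[(2 * half + 1):(2 * half + n * up)]
  y
}

#' Non-negative deconvolution event extraction
#'
#' Upsamples a 30 Hz trace to 150 Hz (polyphase), then solves the
#' non-negative deconvolution problem `min 0.5 * ||y - K s||^2, s >= 0`,
#' where `K` is the causal geometric-decay kernel implied by the 315 ms
#' half-time at 150 Hz, via an exact pool-adjacent-violators scheme (no
#' sparsity penalty). Following the scaling convention, the trace is
#' normalized by its maximum before deconvolution and event amplitudes are
#' multiplied back by that maximum, so amplitudes are directly comparable
#' to noise-floor multiples.
#'
#' @param trace a `fluorescence_trace` or numeric vector at 30 Hz.
#' @param config an [extraction_config()].
#' @param frame_rate_hz input rate; non-30 Hz input is an error unless the
#'   upsample factor is overridden in `config`.
#' @return an `event_series` at the upsampled rate.
#' @export
nnd_events <- function(trace, config = extraction_config(),
                       frame_rate_hz = trace_rate(trace)) {
  v <- trace_values(trace)
  if (abs(frame_rate_hz - 30) > 1e-9 && config$nnd_upsample_factor == 5) {
    abort_calspike("nnd_events expects a 30 Hz trace (override the upsample factor otherwise)",
                   "calspike_bad_rate")
  }
  up <- config$nnd_upsample_factor
  f_hi <- frame_rate_hz * up
  scale <- max(v)
  if (scale <= 0) {
    return(event_series(frame_rate_hz = f_hi))
  }
  y <- resample_poly(v / scale, up)
  gamma <- decay_factor(f_hi, config$half_time_s)
  c_fit <- oasis_nnd_cpp(y, gamma)
  s <- c_fit - gamma * c(0, c_fit[-length(c_fit)])
  tol <- 1e-9 * max(abs(y))
  idx <- which(s > tol)
  event_series(idx, s[idx] * scale, frame_rate_hz = f_hi)
}

#' Post-hoc amplitude thresholding of binned events
#'
#' Bins event amplitudes in `bin_s` windows and zeroes every bin whose
#' summed magnitude is below `k * sigma` (all events in a failing bin are
#' dropped, survivors are returned unchanged). The final partial bin's
#' threshold is pro-rated by its coverage when the trace duration is known.
#'
#' @param events an `event_series`.
#' @param bin_s bin width in seconds (default 100 ms).
#' @param k noise-multiple threshold (>= 0).
#' @param sigma robust noise SD of the source trace.
#' @param duration_s optional trace duration for partial-bin pro-rating.
#' @return the thresholded `event_series`.
#' @export
threshold_binned_events <- function(events, bin_s = 0.1, k, sigma,
                                    duration_s = NULL) {
  stopifnot(k >= 0)
  if (length(events$event_frames) == 0 || k == 0) return(events)
  if (is.infinite(k)) {
    return(event_series(frame_rate_hz = events$frame_rate_hz))
  }
  tt <- event_times(events)
  bin <- floor(tt / bin_s)
  sums <- tapply(events$amplitudes, bin, sum)
  thr <- rep(k * sigma, length(sums))
  if (!is.null(duration_s)) {
    last_bin <- floor((duration_s - 1e-12) / bin_s)
    cover <- (duration_s - last_bin * bin_s) / bin_s
    thr[as.numeric(names(sums)) == last_bin] <- k * sigma * cover
  }
  keep_bins <- as.numeric(names(sums))[sums >= thr]
  keep <- bin %in% keep_bins
  event_series(events$event_frames[keep], events$amplitudes[keep],
               frame_rate_hz = events$frame_rate_hz, source = events$source)
}

#' Benchmark extracted events against ground-truth spikes
#'
#' Divides the recording into `bin_s` bins and classifies each: spike and
#' event present = hit (true positive), spike without event = miss, event
#' without spike = false positive, neither = correct rejection. Also
#' reports the Pearson correlation between binned event amplitude and
#' binned spike count (0 with `correlation_defined = FALSE` when
#' degenerate), the false-positive rate `P(event | no spike)`, and the
#' total event amplitude.
#'
#' @param events an `event_series`.
#' @param true_spike_times ground-truth spike times (s).
#' @param bin_s classification bin width (s).
#' @param duration_s recording duration (s).
#' @return an object of class `gt_benchmark` (a list of counts and rates).
#' @export
benchmark_against_ground_truth <- function(events, true_spike_times,
                                           bin_s = 0.1, duration_s) {
  n_bins <- max(1L, as.integer(ceiling(duration_s / bin_s)))
  clamp <- function(i) pmin(pmax(i, 1L), n_bins)
  spike_counts <- tabulate(clamp(floor(true_spike_times / bin_s) + 1L), n_bins)
  amp <- numeric(n_bins)
  if (length(events$event_frames)) {
    b <- clamp(floor(event_times(events) / bin_s) + 1L)
    for (i in seq_along(b)) amp[b[i]] <- amp[b[i]] + events$amplitudes[i]
  }
  sp <- spike_counts > 0; evb <- amp > 0
  hit <- sum(sp & evb); miss <- sum(sp & !evb)
  fp <- sum(!sp & evb); cr <- sum(!sp & !evb)
  fp_rate <- if (fp + cr > 0) fp / (fp + cr) else 0
  cor_ok <- sd(amp) > 0 && sd(spike_counts) > 0
  rate_cor <- if (cor_ok) cor(amp, spike_counts) else 0
  structure(list(n_bins = n_bins, bin_s = bin_s,
                 hit = hit, miss = miss, false_positive = fp,
                 correct_reject = cr, fp_rate = fp_rate,
                 rate_correlation = rate_cor,
                 correlation_defined = cor_ok,
                 total_event_amplitude = sum(amp)),
            class = "gt_benchmark")
}

#' Threshold sweep of a ground-truth benchmark
#'
#' Applies [threshold_binned_events()] for each noise multiple in the
#' config's threshold grid and benchmarks the surviving events, reporting
#' the false-positive rate, rate correlation, and response amplitude
#' relative to the unthresholded (k = 0) value.
#'
#' @param events an `event_series`.
#' @param true_spike_times ground-truth spike times (s).
#' @param sigma robust noise SD of the source trace.
#' @param duration_s recording duration (s).
#' @param config an [extraction_config()].
#' @param bin_s classification bin width (s).
#' @return a `data.frame` with one row per threshold multiple.
#' @export
benchmark_threshold_sweep <- function(events, true_spike_times, sigma,
                                      duration_s,
                                      config = extraction_config(),
                                      bin_s = 0.1) {
  rows <- lapply(config$threshold_grid, function(k) {
    ev_k <- threshold_binned_events(events, bin_s = bin_s, k = k,
                                    sigma = sigma, duration_s = duration_s)
    b <- benchmark_against_ground_truth(ev_k, true_spike_times, bin_s,
                                        duration_s)
    data.frame(k = k, fp_rate = b$fp_rate,
               rate_correlation = b$rate_correlation,
               total_event_amplitude = b$total_event_amplitude,
               hit = b$hit, miss = b$miss, false_positive = b$false_positive)
  })
  out <- do.call(rbind, rows)
  base <- out$total_event_amplitude[out$k == min(out$k)]
  out$relative_amplitude <- if (base > 0) out$total_event_amplitude / base else 0
  out
}
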