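#' Forward-model parameters
#'
#' Parameters of the spikes-to-fluorescence forward model with cooperative
#' (Hill-type) indicator binding. Defaults are the calibrated values used
#' throughout: decay time `tau_decay_s` = 0.359 s, unitary transient
#' amplitude `amplitude` = 0.021 dF/F, noise SD `noise_sd` = 0.047 dF/F,
#' Hill exponent `hill_exponent` = 2.42, rise time `rise_time_s` = 0.0034 s,
#' saturation `saturation` = 0.0021, and baseline calcium `baseline_ca` =
#' 0.46 (normalized units; one spike adds one normalized unit of calcium).
#'
#' @param tau_decay_s calcium decay time constant (s).
#' @param amplitude peak dF/F of a unitary transient at baseline calcium.
#' @param noise_sd per-frame additive Gaussian noise SD (dF/F).
#' @param hill_exponent Hill cooperativity exponent (dimensionless).
#' @param rise_time_s fluorescence onset time constant (s).
#' @param saturation indicator saturation parameter (dimensionless).
#' @param baseline_ca resting calcium in normalized units.
#' @param frame_rate_hz output sampling rate (Hz).
#' @return an object of class `forward_model_params`.
#' @export
forward_model_params <- function(tau_decay_s = 0.359,
                                 amplitude = 0.021,
                                 noise_sd = 0.047,
                                 hill_exponent = 2.42,
                                 rise_time_s = 0.0034,
                                 saturation = 0.0021,
                                 baseline_ca = 0.46,
                                 frame_rate_hz = 30) {
  stopifnot(tau_decay_s > 0, amplitude > 0, noise_sd >= 0,
            hill_exponent > 0, rise_time_s > 0, saturation >= 0,
            baseline_ca > 0, frame_rate_hz > 0)
  structure(as.list(environment()), class = "forward_model_params")
}

#' Sample per-neuron forward-model parameter variability
#'
#' Draws `n` parameter sets whose amplitude, decay time, and noise SD vary
#' lognormally around the base values, mimicking the spread of per-neuron
#' autocalibration estimates.
#'
#' @param base a [forward_model_params()].
#' @param n number of parameter sets.
#' @param sdlog lognormal sd (log units) applied to A, tau, and sigma.
#' @param seed reproducibility seed.
#' @return a list of `forward_model_params`.
#' @export
sample_forward_params <- function(base = forward_model_params(), n, sdlog = 0.3,
                                  seed = 1) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    p <- base
    p$amplitude <- base$amplitude * rlnorm(1, 0, sdlog)
    p$tau_decay_s <- base$tau_decay_s * rlnorm(1, 0, sdlog)
    p$noise_sd <- base$noise_sd * rlnorm(1, 0, sdlog)
    p
  }))
}

hill <- function(c, n, gamma) c^n / (1 + gamma * c^n)

#' Transform a spike train into a synthetic 30 Hz dF/F trace
#'
#' Latent calcium relaxes exponentially toward `baseline_ca` with time
#' constant `tau_decay_s` and jumps by one normalized unit per spike (frame
#' discretization: `c <- c0 + (c + s - c0) * exp(-dt/tau)` with `s` the spike
#' count in the frame). Fluorescence is a saturating Hill function of
#' calcium, normalized so that a unitary calcium increment at baseline
#' yields a transient of peak `amplitude`, low-pass filtered with time
#' constant `rise_time_s`, with zero-mean Gaussian noise of SD `noise_sd`
#' added per frame. Supralinearity of burst amplitudes follows from the
#' Hill exponent > 1.
#'
#' @param spike_times spike times in seconds, sorted, within
#'   \[0, duration_s\].
#' @param duration_s trace duration (s); must be positive.
#' @param params a [forward_model_params()].
#' @param seed seed for the noise draw (`NULL` uses the ambient RNG).
#' @param keep_calcium if `TRUE`, the latent calcium state is retained in
#'   the result (used by tests and parameter-recovery fits).
#' @return an object of class `fluorescence_trace`: list with `values`,
#'   `frame_rate_hz`, `t_start_s`, and optionally `calcium`.
#' @export
spikes_to_fluorescence <- function(spike_times, duration_s,
                                   params = forward_model_params(),
                                   seed = NULL, keep_calcium = FALSE) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort_calspike("duration_s must be positive", "calspike_bad_duration")
  }
  if (length(spike_times) && is.unsorted(spike_times)) {
    abort_calspike("spike_times must be sorted", "calspike_unsorted_spikes")
  }
  if (length(spike_times) &&
      (min(spike_times) < 0 || max(spike_times) > duration_s)) {
    abort_calspike("spikes outside [0, duration_s]", "calspike_spikes_range")
  }
  f <- params$frame_rate_hz
  n_frames <- as.integer(ceiling(duration_s * f))
  dt <- 1 / f
  frame <- pmin(floor(spike_times * f) + 1L, n_frames)
  s <- tabulate(frame, nbins = n_frames)

  alpha <- exp(-dt / params$tau_decay_s)
  # c_t - c0 = alpha * (c_{t-1} - c0 + s_t): linear AR(1) in the excess
  excess <- as.numeric(stats::filter(alpha * s, alpha, method = "recursive"))
  ca <- params$baseline_ca + excess

  c0 <- params$baseline_ca
  denom <- hill(c0 + 1, params$hill_exponent, params$saturation) -
    hill(c0, params$hill_exponent, params$saturation)
  f_clean <- params$amplitude *
    (hill(ca, params$hill_exponent, params$saturation) -
       hill(c0, params$hill_exponent, params$saturation)) / denom

  beta <- exp(-dt / params$rise_time_s)
  f_rise <- as.numeric(stats::filter((1 - beta) * f_clean, beta,
                                     method = "recursive"))

  values <- if (params$noise_sd > 0) {
    f_rise + with_seed(seed, rnorm(n_frames, 0, params$noise_sd))
  } else f_rise

  out <- list(values = values, frame_rate_hz = f, t_start_s = 0,
              params = params)
  if (keep_calcium) out$calcium <- ca
  structure(out, class = "fluorescence_trace")
}

#' Fit the calcium decay constant after an isolated spike
#'
#' Least-squares fit of a single exponential to the noiseless latent-calcium
#' relaxation toward baseline following one spike; used for forward-model
#' self-consistency checks.
#'
#' @param params a [forward_model_params()].
#' @param fit_window_s portion of the relaxation used for the fit.
#' @return the fitted time constant in seconds.
#' @export
fit_decay_constant <- function(params = forward_model_params(),
                               fit_window_s = 2) {
  p <- params
  p$noise_sd <- 0
  tr <- spikes_to_fluorescence(1, duration_s = 1 + fit_window_s + 1,
                               params = p, keep_calcium = TRUE)
  f <- p$frame_rate_hz
  i0 <- floor(1 * f) + 1L  # frame containing the spike
  idx <- seq(i0, i0 + round(fit_window_s * f))
  excess <- tr$calcium[idx] - p$baseline_ca
  tt <- (idx - i0) / f
  fit <- stats::lm(log(excess) ~ tt)
  -1 / unname(coef(fit)[2])
}
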