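# Independent oracles used by the tests. These deliberately re-derive the
# quantities by brute force / first principles, separate from the package's
# code paths.

# Exhaustive-enumeration minimum of the L0 changepoint objective: every
# subset of changepoint positions, each segment fitted by least squares to
# a geometric decay from its own start.
brute_force_l0 <- function(y, gamma, lam) {
  T <- length(y)
  seg_cost <- matrix(NA_real_, T, T)
  for (s in 1:T) {
    for (t in s:T) {
      k <- 0:(t - s); gk <- gamma^k
      A <- sum(y[s:t] * gk); B <- sum(gk^2); D <- sum(y[s:t]^2)
      seg_cost[s, t] <- 0.5 * (D - A^2 / B)
    }
  }
  best <- Inf
  for (mask in 0:(2^(T - 1) - 1)) {
    cps <- which(bitwAnd(mask, 2^(0:(T - 2))) > 0) + 1
    starts <- c(1, cps); ends <- c(cps - 1, T)
    cost <- lam * length(cps)
    for (j in seq_along(starts)) cost <- cost + seg_cost[starts[j], ends[j]]
    if (cost < best) best <- cost
  }
  best
}

# Generic non-negative least squares min 0.5*||y - K s||^2, s >= 0, by
# projected gradient on the small dense instance.
nnls_oracle <- function(y, gamma, n_iter = 20000) {
  T <- length(y)
  K <- outer(seq_len(T), seq_len(T),
             function(i, j) ifelse(i >= j, gamma^(i - j), 0))
  L <- max(colSums(abs(crossprod(K))))  # crude Lipschitz bound
  s <- rep(0, T)
  KtK <- crossprod(K); Kty <- crossprod(K, y)
  for (it in seq_len(n_iter)) {
    g <- KtK %*% s - Kty
    s <- pmax(s - g / L, 0)
  }
  list(s = as.numeric(s), objective = 0.5 * sum((y - K %*% s)^2))
}

# Direct evaluation of the Jensen-Shannon distance (log base 2) from two
# count/probability vectors.
js_oracle <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  term <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / m[i]))
  }
  sqrt((term(p) + term(q)) / 2)
}

# A small session for tests: full condition grids but few repeats, short
# movie clip and spontaneous epoch, so the stimulus structure is intact at
# a fraction of the duration.
quick_session <- function(seed = 1, dg_repeats = 3, spont_s = 120) {
  make_session(seed = seed, dg_repeats = dg_repeats, sg_repeats = 1,
               ns_repeats = 1, nm_repeats = 2, clip_duration_s = 5,
               spontaneous_duration_s = spont_s)
}

# A bare synthetic unit with a given spike train (for QC / bias tests).
fake_unit <- function(id, spike_times, duration_s,
                      layer = "L5", waveform = 0.6) {
  structure(list(unit_id = id, spike_times = spike_times,
                 tuning = list(baseline_rate_hz = length(spike_times) / duration_s,
                               responsive_flag_truth = TRUE),
                 layer = layer, area = "V1", running_fraction = 0.5,
                 waveform_duration_ms = waveform,
                 contamination_fraction_truth = 0,
                 duration_s = duration_s),
            class = "synthetic_unit")
}

# Poisson spike train with an absolute refractory period.
refractory_poisson <- function(rate_hz, duration_s, refractory_s = 0.003) {
  t <- 0; out <- numeric(0)
  while (t < duration_s) {
    t <- t + refractory_s + rexp(1, rate_hz)
    if (t < duration_s) out <- c(out, t)
  }
  out
}
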