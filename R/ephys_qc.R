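#' ISI violations score
#'
#' Relative-contamination estimate from refractory-period violations:
#' `score = (n_violations * duration_s) / (2 * N^2 * (isi_threshold_s -
#' min_isi_s))`, where `n_violations` is the number of inter-spike
#' intervals shorter than `isi_threshold_s` and `N` the spike count. Under
#' independent contamination the score approximates the relative rate of
#' contaminating spikes; it is invariant to uniform time dilation when the
#' threshold and duration are dilated together.
#'
#' @param spike_times spike times in seconds (sorted).
#' @param duration_s recording duration (s).
#' @param isi_threshold_s refractory threshold (default 1.5 ms).
#' @param min_isi_s censored minimum ISI (default 0).
#' @return the score (>= 0); 0 with attribute `flag = "too_few_spikes"` for
#'   fewer than two spikes.
#' @export
isi_violations_score <- function(spike_times, duration_s,
                                 isi_threshold_s = 0.0015, min_isi_s = 0) {
  n <- length(spike_times)
  if (n < 2) {
    return(structure(0, flag = "too_few_spikes"))
  }
  isi <- diff(spike_times)
  n_viol <- sum(isi < isi_threshold_s)
  (n_viol * duration_s) / (2 * n^2 * (isi_threshold_s - min_isi_s))
}

#' Filter units to regular-spiking, well-isolated ones
#'
#' Keeps units with waveform duration strictly greater than 0.4 ms
#' (regular spiking), and, when the fields are present, presence ratio >
#' 0.9, amplitude cutoff < 0.1, and ISI violations score < 0.5.
#'
#' @param units a `data.frame` with a `waveform_duration_ms` column and
#'   optionally `presence_ratio`, `amplitude_cutoff`,
#'   `isi_violations_score`.
#' @param waveform_min_ms regular-spiking threshold (default 0.4).
#' @return the retained rows.
#' @export
filter_regular_spiking <- function(units, waveform_min_ms = 0.4) {
  keep <- units$waveform_duration_ms > waveform_min_ms
  if ("presence_ratio" %in% names(units)) {
    keep <- keep & units$presence_ratio > 0.9
  }
  if ("amplitude_cutoff" %in% names(units)) {
    keep <- keep & units$amplitude_cutoff < 0.1
  }
  if ("isi_violations_score" %in% names(units)) {
    keep <- keep & units$isi_violations_score < 0.5
  }
  units[keep, , drop = FALSE]
}

# Smoothed log10-ISI histogram: 10 bins per decade, 3-bin moving average.
log_isi_histogram <- function(isi) {
  lg <- log10(isi)
  lo <- floor(min(lg) * 10) / 10
  hi <- ceiling(max(lg) * 10) / 10
  if (hi <= lo) hi <- lo + 0.1
  edges <- seq(lo, hi, by = 0.1)
  if (edges[length(edges)] < hi) edges <- c(edges, edges[length(edges)] + 0.1)
  counts <- tabulate(pmin(findInterval(lg, edges, rightmost.closed = TRUE),
                          length(edges) - 1), length(edges) - 1)
  sm <- as.numeric(stats::filter(counts, rep(1 / 3, 3), sides = 2))
  sm[is.na(sm)] <- counts[is.na(sm)]
  centers <- 10^((edges[-1] + edges[-length(edges)]) / 2)
  list(centers = centers, counts = sm)
}

# indices of local maxima (strictly above left neighbor, at least right);
# zero-padded so peaks in the first/last bin count
find_peaks <- function(h) {
  hp <- c(0, h, 0)
  n <- length(hp)
  which(vapply(seq(2, n - 1), function(i) {
    hp[i] > hp[i - 1] && hp[i] >= hp[i + 1] && hp[i] > 0
  }, logical(1)))
}

#' LogISI burst detection
#'
#' Detects bursts from the smoothed log-ISI histogram: the largest peak at
#' ISI < 50 ms is the intra-burst peak (no such peak means no bursts); for
#' each minimum between that peak and a subsequent peak the void parameter
#' `v = 1 - h_min / sqrt(h_peak1 * h_peak2)` measures peak separability;
#' the ISI at the first minimum with `v > void_threshold` becomes the
#' maxISI cutoff and bursts are runs of more than three spikes with ISIs
#' below it. If no cutoff is found, or maxISI exceeds 50 ms, burst cores
#' are built from sub-50 ms ISIs (>= 3 spikes) and extended by spikes
#' within maxISI of the burst edges.
#'
#' @param spike_times spike times in seconds (>= 4 spikes for any burst).
#' @param void_threshold void-parameter threshold (default 0.7).
#' @param min_burst_spikes spikes per burst on the primary path (default 4,
#'   reading "more than three" literally; the fallback path admits 3).
#' @return an object of class `burst_set`: list with `bursts` (data.frame
#'   `start_s`, `stop_s`, `n_spikes`), `max_isi_s`, `burst_fraction`, and
#'   `void_parameters`.
#' @export
detect_bursts_logisi <- function(spike_times, void_threshold = 0.7,
                                 min_burst_spikes = 4) {
  empty <- structure(list(bursts = data.frame(start_s = numeric(0),
                                              stop_s = numeric(0),
                                              n_spikes = integer(0)),
                          max_isi_s = NA_real_, burst_fraction = 0,
                          void_parameters = numeric(0)),
                     class = "burst_set")
  n <- length(spike_times)
  if (n < 4) return(empty)
  isi <- diff(spike_times)
  isi <- pmax(isi, 1e-6)
  h <- log_isi_histogram(isi)
  peaks <- find_peaks(h$counts)
  intra_candidates <- peaks[h$centers[peaks] < 0.05]
  if (length(intra_candidates) == 0) return(empty)
  p1 <- intra_candidates[which.max(h$counts[intra_candidates])]
  later <- peaks[peaks > p1]
  voids <- numeric(0)
  max_isi <- NA_real_
  for (p2 in later) {
    seg <- seq(p1, p2)
    i_min <- seg[which.min(h$counts[seg])]
    v <- 1 - h$counts[i_min] / sqrt(h$counts[p1] * h$counts[p2])
    voids <- c(voids, v)
    if (is.na(max_isi) && v > void_threshold) {
      max_isi <- h$centers[i_min]
    }
  }

  runs_to_bursts <- function(short, min_spikes) {
    r <- rle(short)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values & (r$lengths + 1 >= min_spikes)
    data.frame(first = starts[keep], last = ends[keep] + 1)  # spike indices
  }

  if (!is.na(max_isi) && max_isi <= 0.05) {
    b <- runs_to_bursts(isi < max_isi, min_burst_spikes)
  } else {
    # fallback: sub-50 ms cores (>= 3 spikes), extended by spikes within
    # maxISI of the edges when a cutoff exists
    b <- runs_to_bursts(isi < 0.05, 3)
    if (!is.na(max_isi) && nrow(b)) {
      for (j in seq_len(nrow(b))) {
        while (b$first[j] > 1 && isi[b$first[j] - 1] < max_isi &&
               (j == 1 || b$first[j] - 1 > b$last[j - 1])) {
          b$first[j] <- b$first[j] - 1
        }
        while (b$last[j] < n && isi[b$last[j]] < max_isi &&
               (j == nrow(b) || b$last[j] + 1 < b$first[j + 1])) {
          b$last[j] <- b$last[j] + 1
        }
      }
    }
  }
  if (nrow(b) == 0) {
    out <- empty
    out$max_isi_s <- max_isi
    out$void_parameters <- voids
    return(out)
  }
  bursts <- data.frame(start_s = spike_times[b$first],
                       stop_s = spike_times[b$last],
                       n_spikes = b$last - b$first + 1L)
  structure(list(bursts = bursts, max_isi_s = max_isi,
                 burst_fraction = sum(bursts$n_spikes) / n,
                 void_parameters = voids),
            class = "burst_set")
}

#' QC metric table for a population
#'
#' @param population a `synthetic_population` or list of `synthetic_unit`.
#' @return a `data.frame` keyed by `unit_id` with firing rate, ISI
#'   violations score, burst fraction, and the carried unit attributes.
#' @export
qc_metrics <- function(population) {
  units <- if (inherits(population, "synthetic_population")) {
    population$units
  } else population
  rows <- lapply(units, function(u) {
    data.frame(unit_id = u$unit_id,
               firing_rate_hz = length(u$spike_times) / u$duration_s,
               isi_violations_score = as.numeric(
                 isi_violations_score(u$spike_times, u$duration_s)),
               burst_fraction = detect_bursts_logisi(u$spike_times)$burst_fraction,
               waveform_duration_ms = u$waveform_duration_ms,
               layer = u$layer, area = u$area,
               running_fraction = u$running_fraction,
               contamination_fraction_truth = u$contamination_fraction_truth,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
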