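#' Per-trial response magnitudes
#'
#' The response magnitude for a trial is the number of spikes (ephys) or
#' the summed event amplitude (imaging) falling in the half-open interval
#' \[start, stop). The same code path serves both modalities; only the
#' definition of magnitude differs.
#'
#' @param activity a numeric vector of spike times (seconds) or an
#'   `event_series`.
#' @param stimulus_table a stimulus table (rows are trials).
#' @return a `data.frame` with `trial_id`, `condition_id`, `stimulus_type`,
#'   `magnitude`, and `modality` (`"ephys"` or `"imaging"`).
#' @export
trial_response_magnitudes <- function(activity, stimulus_table) {
  if (inherits(activity, "event_series")) {
    tt <- event_times(activity)
    ww <- activity$amplitudes
    modality <- "imaging"
  } else {
    tt <- as.numeric(activity)
    ww <- rep(1, length(tt))
    modality <- "ephys"
  }
  o <- order(tt)
  tt <- tt[o]; ww <- ww[o]
  cw <- c(0, cumsum(ww))
  # half-open [start, stop): #{t < stop} - #{t < start}
  lo <- findInterval(stimulus_table$start_s, tt, left.open = TRUE)
  hi <- findInterval(stimulus_table$stop_s, tt, left.open = TRUE)
  mag <- cw[hi + 1] - cw[lo + 1]
  end_time <- if (length(tt)) max(tt) else 0
  if (any(stimulus_table$start_s > end_time)) {
    warning("some trials lie outside the activity time range; magnitudes set to 0")
  }
  data.frame(trial_id = stimulus_table$trial_id,
             condition_id = stimulus_table$condition_id,
             stimulus_type = stimulus_table$stimulus_type,
             magnitude = mag,
             modality = modality,
             stringsAsFactors = FALSE)
}

#' Response reliability against a spontaneous null
#'
#' Builds a null distribution by measuring the unit's activity in `n_draws`
#' intervals of the trial duration placed uniformly at random inside the
#' spontaneous (gray-screen) epoch. Reliability is the percentage of
#' preferred-condition trials whose magnitude is strictly larger than at
#' least 95% of the null magnitudes; a unit is responsive when reliability
#' exceeds `threshold` (default 25; a stricter 40 is used when matching
#' ephys to imaging class distributions).
#'
#' @param activity spike times or an `event_series`.
#' @param trials the preferred-condition trials (rows of a stimulus table).
#' @param spontaneous numeric `c(start_s, stop_s)` of the spontaneous epoch.
#' @param n_draws number of null intervals (default 1000).
#' @param seed reproducibility seed for the null placement.
#' @param threshold responsiveness threshold in percent.
#' @param null_quantile fraction of null draws a trial must beat (0.95).
#' @return a list with `reliability` (percent), `responsive` (logical), and
#'   `null_magnitudes`.
#' @export
response_reliability <- function(activity, trials, spontaneous,
                                 n_draws = 1000, seed = 1, threshold = 25,
                                 null_quantile = 0.95) {
  if (nrow(trials) == 0) {
    abort_calspike("no preferred-condition trials", "calspike_no_trials")
  }
  dur <- trials$stop_s[1] - trials$start_s[1]
  span <- spontaneous[2] - spontaneous[1]
  if (span <= dur) {
    abort_calspike("spontaneous epoch shorter than trial duration",
                   "calspike_short_spontaneous")
  }
  starts <- with_seed(seed, runif(n_draws, spontaneous[1], spontaneous[2] - dur))
  null_tbl <- data.frame(trial_id = seq_len(n_draws),
                         condition_id = "null", stimulus_type = "spontaneous",
                         start_s = starts, stop_s = starts + dur)
  null_mag <- suppressWarnings(
    trial_response_magnitudes(activity, null_tbl)$magnitude)
  trial_mag <- suppressWarnings(
    trial_response_magnitudes(activity, trials)$magnitude)
  need <- ceiling(null_quantile * n_draws)
  beats <- vapply(trial_mag, function(m) sum(null_mag < m) >= need, logical(1))
  reliability <- 100 * mean(beats)
  list(reliability = reliability,
       responsive = reliability > threshold,
       null_magnitudes = null_mag)
}

#' Lifetime sparseness
#'
#' Nonparametric selectivity of a per-condition mean-response vector:
#' `S = (1 - (sum(r)/n)^2 / (sum(r^2)/n)) / (1 - 1/n)`, equal to 0 for a
#' flat responder and 1 for a single-condition responder. Invariant to
#' positive scaling of `r`.
#'
#' @param r non-negative per-condition mean response magnitudes (n >= 2).
#' @return sparseness in \[0, 1\]; `NA` (with attribute `flag =
#'   "all_zero"`) when every entry is zero.
#' @export
lifetime_sparseness <- function(r) {
  n <- length(r)
  stopifnot(n >= 2)
  if (any(r < 0)) {
    abort_calspike("response magnitudes must be non-negative",
                   "calspike_negative_response")
  }
  if (all(r == 0)) {
    return(structure(NA_real_, flag = "all_zero"))
  }
  s <- (1 - (sum(r) / n)^2 / (sum(r^2) / n)) / (1 - 1 / n)
  min(max(s, 0), 1)
}

#' Global orientation selectivity index
#'
#' `gOSI = |sum_theta r(theta) exp(2i theta)| / sum_theta r(theta)` over the
#' mean responses to the 8 drifting-grating directions (averaged across
#' temporal frequencies).
#'
#' @param r mean responses per direction.
#' @param directions_deg directions in degrees (default the standard 8).
#' @return gOSI in \[0, 1\]; `NA` for an all-zero vector.
#' @export
gOSI <- function(r, directions_deg = seq(0, 315, by = 45)) {
  stopifnot(length(r) == length(directions_deg))
  if (all(r == 0)) return(NA_real_)
  th <- directions_deg * pi / 180
  Mod(sum(r * exp(2i * th))) / sum(r)
}

# Mean magnitude per condition, in a canonical (sorted condition_id) order.
condition_means <- function(response_table) {
  agg <- tapply(response_table$magnitude, response_table$condition_id, mean)
  agg[order(names(agg))]
}

#' Preference metrics from a response table
#'
#' The preferred condition is the condition with the largest mean response;
#' the preferred temporal frequency (drifting gratings) and spatial
#' frequency (static gratings) are the argmax of marginal means averaged
#' across the other condition axes. Ties break toward the lowest condition
#' index, deterministically.
#'
#' @param response_table output of [trial_response_magnitudes()].
#' @param stimulus_table the matching stimulus table (for condition axes).
#' @return a list with `preferred_condition` and, when applicable,
#'   `preferred_temporal_frequency_hz` / `preferred_spatial_frequency_cpd`.
#' @export
preference_metrics <- function(response_table, stimulus_table) {
  cm <- condition_means(response_table)
  pref <- names(cm)[which.max(cm)]  # which.max takes the first maximum
  out <- list(preferred_condition = pref)
  type <- stimulus_table$stimulus_type[1]
  m <- merge(response_table, stimulus_table[, setdiff(names(stimulus_table),
                                                      c("condition_id", "stimulus_type"))],
             by = "trial_id")
  marginal_pref <- function(axis) {
    mm <- tapply(m$magnitude, m[[axis]], mean)
    as.numeric(names(mm)[which.max(mm)])  # names sort ascending numerically
  }
  if (type == "drifting_gratings") {
    out$preferred_temporal_frequency_hz <- marginal_pref("temporal_frequency_hz")
  }
  if (type == "static_gratings") {
    out$preferred_spatial_frequency_cpd <- marginal_pref("spatial_frequency_cpd")
  }
  out
}

#' Full per-unit metric table
#'
#' Computes, for each stimulus type in the session, the response
#' reliability (and responsiveness), lifetime sparseness, gOSI (drifting
#' gratings only), preferred condition / temporal / spatial frequency, and
#' the overall activity rate. Selectivity and preference fields are
#' reported only for responsive units, matching the analysis convention.
#'
#' @param activity spike times or an `event_series`.
#' @param session a stacked stimulus table containing a spontaneous epoch.
#' @param n_draws null draws for reliability.
#' @param seed reproducibility seed.
#' @param threshold responsiveness threshold (percent).
#' @param trial_mask optional logical vector over session rows (e.g.
#'   running trials only); masked-out trials are dropped.
#' @return a `data.frame`, one row per stimulus type.
#' @export
unit_metrics <- function(activity, session, n_draws = 1000, seed = 1,
                         threshold = 25, trial_mask = NULL) {
  if (!is.null(trial_mask)) {
    keep <- trial_mask | session$stimulus_type == "spontaneous"
    session <- session[keep, , drop = FALSE]
  }
  sp <- spontaneous_epoch(session)
  dur <- session_duration(session)
  n_act <- if (inherits(activity, "event_series")) {
    length(activity$event_frames)
  } else length(activity)
  overall_rate <- n_act / dur

  types <- intersect(c("drifting_gratings", "static_gratings",
                       "natural_scenes", "natural_movie"),
                     unique(session$stimulus_type))
  rows <- lapply(types, function(type) {
    tbl <- session[session$stimulus_type == type, , drop = FALSE]
    rt <- suppressWarnings(trial_response_magnitudes(activity, tbl))
    cm <- condition_means(rt)
    pref_id <- names(cm)[which.max(cm)]
    rel <- response_reliability(
      activity, tbl[tbl$condition_id == pref_id, , drop = FALSE],
      sp, n_draws = n_draws, seed = child_seed(seed, match(type, types)),
      threshold = threshold)
    responsive <- rel$responsive
    ls_val <- lifetime_sparseness(as.numeric(cm))
    g <- NA_real_
    pref_tf <- NA_real_; pref_sf <- NA_real_
    if (responsive) {
      prefm <- preference_metrics(rt, tbl)
      if (type == "drifting_gratings") {
        mm <- merge(rt, tbl[, c("trial_id", "direction_deg")], by = "trial_id")
        by_dir <- tapply(mm$magnitude, mm$direction_deg, mean)
        g <- gOSI(as.numeric(by_dir),
                  as.numeric(names(by_dir)))
        pref_tf <- prefm$preferred_temporal_frequency_hz
      }
      if (type == "static_gratings") {
        pref_sf <- prefm$preferred_spatial_frequency_cpd
      }
    }
    data.frame(stimulus_type = type,
               response_reliability = rel$reliability,
               responsive = responsive,
               lifetime_sparseness = if (responsive) as.numeric(ls_val) else NA_real_,
               lifetime_sparseness_raw = as.numeric(ls_val),
               gOSI = g,
               preferred_condition = pref_id,
               preferred_temporal_frequency_hz = pref_tf,
               preferred_spatial_frequency_cpd = pref_sf,
               overall_rate_hz = overall_rate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Metric table for a whole population
#'
#' Applies [unit_metrics()] to every unit of a population (spike trains) or
#' to a list of event series, returning a stacked table keyed by `unit_id`.
#'
#' @param activities a `synthetic_population`, a list of spike-time vectors,
#'   or a list of `event_series`.
#' @param session a stacked stimulus table.
#' @param ... passed to [unit_metrics()].
#' @return a `data.frame`, one row per unit x stimulus type.
#' @export
population_metrics <- function(activities, session, ...) {
  if (inherits(activities, "synthetic_population")) {
    ids <- vapply(activities$units, `[[`, numeric(1), "unit_id")
    activities <- lapply(activities$units, `[[`, "spike_times")
  } else {
    ids <- names(activities) %||% seq_along(activities)
  }
  rows <- lapply(seq_along(activities), function(i) {
    m <- unit_metrics(activities[[i]], session, ...)
    m$unit_id <- ids[i]
    m
  })
  do.call(rbind, rows)
}
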