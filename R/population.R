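#' Specification of a synthetic population
#'
#' Parameters of the ground-truth population generator: the number of units,
#' lognormal firing-rate heterogeneity, laminar composition, tuning, burst
#' statistics, and the truth fraction of responsive units. Rates are in
#' spikes/s; `rate_meanlog`/`rate_sdlog` parameterize the lognormal
#' distribution of baseline rates (defaults give a geometric mean of 2 Hz
#' with ~1 log-unit spread, the classic cortical lognormal).
#'
#' @param n_units number of units (> 0).
#' @param rate_meanlog,rate_sdlog lognormal parameters of baseline rate.
#' @param evoked_gain_meanlog,evoked_gain_sdlog lognormal parameters of the
#'   peak-evoked/baseline rate ratio for responsive units.
#' @param p_responsive truth probability that a unit is tuned (others fire at
#'   baseline regardless of the stimulus).
#' @param kappa_direction von Mises concentration of direction tuning.
#' @param tf_width_octaves,sf_width_octaves log-Gaussian tuning widths on the
#'   temporal/spatial-frequency axes.
#' @param scene_rank_width e-folding scale (in preference rank) of natural
#'   scene tuning; smaller is sparser.
#' @param movie_frame_width_frames Gaussian width of movie frame tuning.
#' @param burst_propensity probability of an injected burst on a strongly
#'   driven trial; `burst_size` spikes at 5 ms inter-spike intervals.
#' @param burst_size spikes per injected burst (>= 3).
#' @param layer_fractions named simplex over `L2/3`, `L4`, `L5`, `L6`.
#' @param area cortical area label.
#' @param seed default seed used by [simulate_population()].
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n_units = 50,
                            rate_meanlog = log(2), rate_sdlog = 1,
                            evoked_gain_meanlog = log(4),
                            evoked_gain_sdlog = 0.5,
                            p_responsive = 0.8,
                            kappa_direction = 2,
                            tf_width_octaves = 1,
                            sf_width_octaves = 1,
                            scene_rank_width = 3,
                            movie_frame_width_frames = 15,
                            burst_propensity = 0.3,
                            burst_size = 4,
                            layer_fractions = c("L2/3" = 0.35, "L4" = 0.25,
                                                "L5" = 0.30, "L6" = 0.10),
                            area = "V1",
                            seed = 1) {
  stopifnot(n_units > 0, burst_size >= 3,
            burst_propensity >= 0, burst_propensity <= 1)
  if (abs(sum(layer_fractions) - 1) > 1e-8) {
    abort_calspike("layer_fractions must sum to 1", "calspike_bad_layers")
  }
  structure(as.list(environment()), class = "population_spec")
}

# Tuning value in [0, 1] for each trial of a stimulus table, given a unit's
# tuning spec. Smooth unimodal falloff from the preferred condition.
tuning_values <- function(tuning, table) {
  type <- table$stimulus_type[1]
  if (type == "drifting_gratings") {
    vm <- exp(tuning$kappa_direction *
                (cos((table$direction_deg - tuning$pref_direction_deg) *
                       pi / 180) - 1))
    tf <- exp(-(log2(table$temporal_frequency_hz / tuning$pref_tf_hz))^2 /
                (2 * tuning$tf_width_octaves^2))
    vm * tf
  } else if (type == "static_gratings") {
    vo <- exp(tuning$kappa_direction *
                (cos(2 * (table$orientation_deg - tuning$pref_orientation_deg) *
                       pi / 180) - 1))
    sf <- exp(-(log2(table$spatial_frequency_cpd / tuning$pref_sf_cpd))^2 /
                (2 * tuning$sf_width_octaves^2))
    vo * sf
  } else if (type == "natural_scenes") {
    tuning$scene_values[table$image_id + 1L]
  } else if (type == "natural_movie") {
    exp(-(table$frame_id - tuning$pref_frame)^2 /
          (2 * tuning$movie_frame_width_frames^2))
  } else {
    rep(0, nrow(table))
  }
}

sample_tuning <- function(spec) {
  responsive <- runif(1) < spec$p_responsive
  baseline <- rlnorm(1, spec$rate_meanlog, spec$rate_sdlog)
  gain <- if (responsive) {
    rlnorm(1, spec$evoked_gain_meanlog, spec$evoked_gain_sdlog)
  } else 1
  ranks <- sample.int(118) - 1L  # preference rank of each image
  list(
    baseline_rate_hz = baseline,
    evoked_peak_rate_hz = baseline * max(1, gain),
    responsive_flag_truth = responsive,
    pref_direction_deg = sample(seq(0, 315, 45), 1),
    pref_tf_hz = sample(c(1, 2, 4, 8, 15), 1),
    pref_orientation_deg = sample(seq(0, 150, 30), 1),
    pref_sf_cpd = sample(c(0.02, 0.04, 0.08, 0.16, 0.32), 1),
    pref_frame = sample.int(900, 1) - 1L,
    scene_values = exp(-ranks / spec$scene_rank_width),
    kappa_direction = spec$kappa_direction,
    tf_width_octaves = spec$tf_width_octaves,
    sf_width_octaves = spec$sf_width_octaves,
    movie_frame_width_frames = spec$movie_frame_width_frames,
    burst_propensity = spec$burst_propensity,
    burst_size = spec$burst_size
  )
}

#' Simulate a ground-truth spiking population
#'
#' Draws each unit's spikes as an inhomogeneous Poisson process whose
#' per-trial rate falls off smoothly from the preferred condition (von Mises
#' over direction/orientation, log-Gaussian over temporal/spatial frequency,
#' rank-sparse over scenes, Gaussian over movie frames). Bursts
#' (`burst_size` spikes at 5 ms intervals) are injected on strongly driven
#' trials (tuning value >= 0.5) with probability `burst_propensity`. Time not
#' covered by any trial, including the spontaneous epoch and gray gaps,
#' fires at the unit's baseline rate.
#'
#' @param spec a [population_spec()].
#' @param session a stacked stimulus table from [make_session()]; must cover
#'   all four stimulus types and contain a spontaneous epoch.
#' @param seed reproducibility seed (defaults to `spec$seed`).
#' @return an object of class `synthetic_population`: a list of units, each
#'   with `unit_id`, `spike_times` (strictly increasing), `tuning`, `layer`,
#'   `area`, `running_fraction`, `waveform_duration_ms`,
#'   `contamination_fraction_truth`, and `duration_s`.
#' @export
simulate_population <- function(spec, session, seed = spec$seed) {
  types_needed <- c("drifting_gratings", "static_gratings",
                    "natural_scenes", "natural_movie")
  missing <- setdiff(types_needed, unique(session$stimulus_type))
  if (length(missing)) {
    abort_calspike(paste("session lacks stimulus types:",
                         paste(missing, collapse = ", ")),
                   "calspike_incomplete_session")
  }
  spontaneous_epoch(session)  # errors if absent
  dur <- session_duration(session)
  trials <- session[session$stimulus_type != "spontaneous", , drop = FALSE]

  # complement of trial coverage (gaps + spontaneous), for baseline firing
  ord <- order(trials$start_s)
  ts <- trials$start_s[ord]; te <- trials$stop_s[ord]
  gap_start <- c(0, te); gap_stop <- c(ts, dur)
  ok <- gap_stop > gap_start + 1e-12
  gap_start <- gap_start[ok]; gap_stop <- gap_stop[ok]

  units <- with_seed(seed, {
    lapply(seq_len(spec$n_units), function(i) {
      tuning <- sample_tuning(spec)
      tv <- numeric(nrow(trials))
      for (type in types_needed) {
        idx <- trials$stimulus_type == type
        tv[idx] <- tuning_values(tuning, trials[idx, , drop = FALSE])
      }
      rate <- tuning$baseline_rate_hz +
        (tuning$evoked_peak_rate_hz - tuning$baseline_rate_hz) * tv
      tdur <- trials$stop_s - trials$start_s
      counts <- rpois(nrow(trials), rate * tdur)
      times <- rep(trials$start_s, counts) + runif(sum(counts)) * rep(tdur, counts)

      # baseline firing in gaps and the spontaneous epoch
      gdur <- gap_stop - gap_start
      gcounts <- rpois(length(gdur), tuning$baseline_rate_hz * gdur)
      gtimes <- rep(gap_start, gcounts) + runif(sum(gcounts)) * rep(gdur, gcounts)

      # trial-locked bursts on strongly driven trials (tuned units only;
      # an untuned unit has no stimulus-locked drive to burst to)
      btimes <- numeric(0)
      driven <- if (tuning$responsive_flag_truth) which(tv >= 0.5) else integer(0)
      if (length(driven) && tuning$burst_propensity > 0) {
        hit <- driven[runif(length(driven)) < tuning$burst_propensity]
        if (length(hit)) {
          onset <- trials$start_s[hit] +
            runif(length(hit)) * pmax(tdur[hit] / 2, 1e-4)
          btimes <- rep(onset, each = tuning$burst_size) +
            rep(0.005 * (seq_len(tuning$burst_size) - 1), length(hit))
        }
      }

      st <- sort(unique(c(times, gtimes, btimes)))
      st <- st[st >= 0 & st < dur]
      structure(list(
        unit_id = i,
        spike_times = st,
        tuning = tuning,
        layer = sample(names(spec$layer_fractions), 1,
                       prob = spec$layer_fractions),
        area = spec$area,
        running_fraction = rbeta(1, 2, 2),
        waveform_duration_ms = rnorm(1, 0.6, 0.1),
        contamination_fraction_truth = 0,
        duration_s = dur
      ), class = "synthetic_unit")
    })
  })
  structure(list(units = units, spec = spec, seed = seed, session = session),
            class = "synthetic_population")
}

#' Merge a fraction of a donor unit's spikes into a target unit
#'
#' Emulates spike-sorting contamination, in which spikes from a nearby
#' neuron are mistakenly merged into a unit's spike train. A uniformly
#' sampled fraction of the donor's spikes is merged into the target;
#' identical timestamps are collapsed so the train stays strictly
#' increasing. The injected fraction is recorded in
#' `contamination_fraction_truth`.
#'
#' @param target,donor `synthetic_unit` objects (must differ).
#' @param fraction fraction of donor spikes to merge, in \[0, 1\].
#' @param seed reproducibility seed.
#' @return the contaminated target unit.
#' @export
inject_contamination <- function(target, donor, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (identical(target$unit_id, donor$unit_id)) {
    abort_calspike("donor must differ from target", "calspike_self_donor")
  }
  n_take <- round(fraction * length(donor$spike_times))
  take <- with_seed(seed, sample(donor$spike_times, n_take))
  target$spike_times <- sort(unique(c(target$spike_times, take)))
  target$contamination_fraction_truth <- fraction
  target
}

#' Apply ephys-style detection bias to a population
#'
#' Extracellular recording preferentially misses low-rate neurons. Each unit
#' is retained with probability given by a logistic function of its log
#' overall firing rate, centered at `rate_threshold_hz` with slope
#' `detection_slope`; `detection_slope = Inf` gives a hard threshold (units
#' at or above threshold kept) and `rate_threshold_hz = 0` keeps everything.
#'
#' @param units a list of `synthetic_unit` or a `synthetic_population`.
#' @param rate_threshold_hz rate at which detection probability is 50%.
#' @param detection_slope logistic slope on the log-rate axis.
#' @param seed reproducibility seed.
#' @return the retained units (same container type as the input).
#' @export
apply_selection_bias <- function(units, rate_threshold_hz, detection_slope,
                                 seed = 1) {
  stopifnot(rate_threshold_hz >= 0)
  pop <- inherits(units, "synthetic_population")
  ulist <- if (pop) units$units else units
  rates <- vapply(ulist, function(u) {
    length(u$spike_times) / u$duration_s
  }, numeric(1))
  p_keep <- if (rate_threshold_hz == 0) {
    rep(1, length(rates))
  } else if (is.infinite(detection_slope)) {
    as.numeric(rates >= rate_threshold_hz)
  } else {
    plogis(detection_slope * (log(pmax(rates, 1e-12)) - log(rate_threshold_hz)))
  }
  keep <- with_seed(seed, runif(length(ulist)) < p_keep)
  if (pop) {
    units$units <- ulist[keep]
    units
  } else {
    ulist[keep]
  }
}
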