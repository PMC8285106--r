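#' Write/read the plain-text exchange formats
#'
#' A simulated population serializes to a directory of plain-text files:
#' `trials.csv` (the stimulus table), `spikes.csv` (`unit_id`,
#' `spike_time_s`), `units.csv` (per-unit attributes), and `manifest.json`
#' (the population spec and seed). Event series serialize to CSV with
#' `unit_id`, `frame`, `time_s`, `amplitude`; trace matrices to CSV (units
#' x frames) with a JSON sidecar carrying frame rate, parameters and seed.
#'
#' @param population a `synthetic_population`.
#' @param dir output directory (created if needed).
#' @return `write_population`: the directory, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(population$session, file.path(dir, "trials.csv"),
            row.names = FALSE)
  spikes <- do.call(rbind, lapply(population$units, function(u) {
    if (!length(u$spike_times)) return(NULL)
    data.frame(unit_id = u$unit_id, spike_time_s = u$spike_times)
  }))
  write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  units <- do.call(rbind, lapply(population$units, function(u) {
    data.frame(unit_id = u$unit_id, layer = u$layer, area = u$area,
               running_fraction = u$running_fraction,
               waveform_duration_ms = u$waveform_duration_ms,
               contamination_fraction_truth = u$contamination_fraction_truth,
               duration_s = u$duration_s,
               baseline_rate_hz = u$tuning$baseline_rate_hz,
               responsive_flag_truth = u$tuning$responsive_flag_truth)
  }))
  write.csv(units, file.path(dir, "units.csv"), row.names = FALSE)
  manifest <- unclass(population$spec)
  manifest$layer_fractions <- as.list(manifest$layer_fractions)
  jsonlite::write_json(list(spec = manifest, seed = population$seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_population
#' @return `read_spikes_csv`: a named list of spike-time vectors.
#' @export
read_spikes_csv <- function(dir) {
  sp <- read.csv(file.path(dir, "spikes.csv"))
  split(sp$spike_time_s, sp$unit_id)
}

#' @rdname write_population
#' @param events_by_unit a named list of `event_series`.
#' @param path output CSV path.
#' @export
write_events_csv <- function(events_by_unit, path) {
  rows <- lapply(names(events_by_unit), function(id) {
    ev <- events_by_unit[[id]]
    if (!length(ev$event_frames)) return(NULL)
    data.frame(unit_id = id, frame = ev$event_frames,
               time_s = event_times(ev), amplitude = ev$amplitudes)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$unit_id), function(d) {
    event_series(d$frame, d$amplitude,
                 frame_rate_hz = attr(df, "frame_rate_hz") %||% 30)
  })
}

#' @rdname write_population
#' @param traces a list of `fluorescence_trace` (equal lengths) or a
#'   numeric matrix (units x frames).
#' @param frame_rate_hz,seed sidecar metadata.
#' @export
write_traces_csv <- function(traces, path, frame_rate_hz = 30, seed = NULL) {
  if (is.list(traces) && inherits(traces[[1]], "fluorescence_trace")) {
    frame_rate_hz <- traces[[1]]$frame_rate_hz
    traces <- do.call(rbind, lapply(traces, `[[`, "values"))
  }
  write.table(traces, path, sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(frame_rate_hz = frame_rate_hz, seed = seed,
                            n_units = nrow(traces), n_frames = ncol(traces)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_traces_csv <- function(path) {
  m <- as.matrix(read.table(path, sep = ","))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  attr(m, "frame_rate_hz") <- meta$frame_rate_hz
  m
}
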