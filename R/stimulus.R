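#' Stimulus tables for the four standard stimulus classes
#'
#' Builds a trial table for one stimulus type using the standard visual
#' coding condition grids: drifting gratings (8 directions x 5 temporal
#' frequencies, 2 s on + 1 s gray), static gratings (5 spatial frequencies x
#' 6 orientations x 4 phases, 0.25 s, no gap), natural scenes (118 images,
#' 0.25 s, no gap), natural movies (contiguous 1/30 s frame trials), and a
#' single spontaneous (mean-luminance gray) epoch. Grating/scene trials are
#' presented in seeded random order; movie frames are contiguous.
#'
#' @param stimulus_type one of `"drifting_gratings"`, `"static_gratings"`,
#'   `"natural_scenes"`, `"natural_movie"`, `"spontaneous"`.
#' @param repeats number of presentations of each condition (for movies, the
#'   number of clip repeats). Must be >= 1.
#' @param seed integer seed controlling presentation order.
#' @param start_s session time at which the block begins.
#' @param clip_duration_s movie clip length in seconds (30 for Natural Movie
#'   One, 120 for Natural Movie Three).
#' @param spontaneous_duration_s length of the spontaneous epoch.
#' @return a `data.frame` with columns `trial_id`, `stimulus_type`,
#'   `start_s`, `stop_s`, `condition_id` plus the condition variables that
#'   apply to the stimulus type (`direction_deg`, `temporal_frequency_hz`,
#'   `spatial_frequency_cpd`, `orientation_deg`, `phase`, `image_id`,
#'   `frame_id`).
#' @examples
#' dg <- make_stimulus_table("drifting_gratings", repeats = 15, seed = 1)
#' nrow(dg)  # 600 presentations
#' @export
make_stimulus_table <- function(stimulus_type, repeats = 1, seed = 1,
                                start_s = 0,
                                clip_duration_s = 30,
                                spontaneous_duration_s = 300) {
  types <- c("drifting_gratings", "static_gratings", "natural_scenes",
             "natural_movie", "spontaneous")
  if (!is.character(stimulus_type) || length(stimulus_type) != 1 ||
      !(stimulus_type %in% types)) {
    abort_calspike(sprintf("unknown stimulus_type: %s",
                           paste(stimulus_type, collapse = ", ")),
                   "calspike_bad_stimulus_type")
  }
  if (stimulus_type != "spontaneous" && (!is.numeric(repeats) || repeats < 1)) {
    abort_calspike("repeats must be >= 1", "calspike_bad_repeats")
  }

  if (stimulus_type == "drifting_gratings") {
    grid <- expand.grid(direction_deg = seq(0, 315, by = 45),
                        temporal_frequency_hz = c(1, 2, 4, 8, 15))
    grid$spatial_frequency_cpd <- 0.04
    tbl <- grid[rep(seq_len(nrow(grid)), repeats), , drop = FALSE]
    tbl <- with_seed(seed, tbl[sample.int(nrow(tbl)), , drop = FALSE])
    dur <- 2; gap <- 1
    tbl$condition_id <- sprintf("dg_dir%03d_tf%02g", tbl$direction_deg,
                                tbl$temporal_frequency_hz)
  } else if (stimulus_type == "static_gratings") {
    grid <- expand.grid(spatial_frequency_cpd = c(0.02, 0.04, 0.08, 0.16, 0.32),
                        orientation_deg = seq(0, 150, by = 30),
                        phase = c(0, 0.25, 0.5, 0.75))
    tbl <- grid[rep(seq_len(nrow(grid)), repeats), , drop = FALSE]
    tbl <- with_seed(seed, tbl[sample.int(nrow(tbl)), , drop = FALSE])
    dur <- 0.25; gap <- 0
    tbl$condition_id <- sprintf("sg_sf%.2f_or%03d_ph%.2f",
                                tbl$spatial_frequency_cpd,
                                tbl$orientation_deg, tbl$phase)
  } else if (stimulus_type == "natural_scenes") {
    grid <- data.frame(image_id = 0:117)
    tbl <- grid[rep(seq_len(nrow(grid)), repeats), , drop = FALSE]
    tbl <- with_seed(seed, tbl[sample.int(nrow(tbl)), , drop = FALSE])
    names(tbl) <- "image_id"
    dur <- 0.25; gap <- 0
    tbl$condition_id <- sprintf("ns_img%03d", tbl$image_id)
  } else if (stimulus_type == "natural_movie") {
    n_frames <- round(clip_duration_s * 30)
    tbl <- data.frame(frame_id = rep(seq_len(n_frames) - 1L, repeats))
    dur <- 1 / 30; gap <- 0
    tbl$condition_id <- sprintf("nm_f%04d", tbl$frame_id)
  } else {  # spontaneous
    tbl <- data.frame(condition_id = "spontaneous")
    dur <- spontaneous_duration_s; gap <- 0
  }

  n <- nrow(tbl)
  tbl$trial_id <- seq_len(n)
  tbl$stimulus_type <- stimulus_type
  tbl$start_s <- start_s + (seq_len(n) - 1) * (dur + gap)
  tbl$stop_s <- tbl$start_s + dur
  rownames(tbl) <- NULL
  front <- c("trial_id", "stimulus_type", "start_s", "stop_s", "condition_id")
  tbl[, c(front, setdiff(names(tbl), front)), drop = FALSE]
}

#' Assemble a full synthetic session
#'
#' Stacks one block per stimulus type plus a single terminal spontaneous
#' epoch into a non-overlapping, time-ordered session table. Defaults follow
#' the standard protocol (15 drifting-grating repeats, ~50 static-grating
#' and natural-scene repeats, a 30 s movie repeated 10 times); scale the
#' repeat counts down for quick experiments.
#'
#' @param seed seed for per-block presentation order.
#' @param dg_repeats,sg_repeats,ns_repeats,nm_repeats repeats per block.
#' @param clip_duration_s movie clip length (seconds).
#' @param spontaneous_duration_s spontaneous epoch length (seconds).
#' @return a stacked stimulus `data.frame` (see [make_stimulus_table()]);
#'   trial ids are renumbered session-wide.
#' @export
make_session <- function(seed = 1, dg_repeats = 15, sg_repeats = 50,
                         ns_repeats = 50, nm_repeats = 10,
                         clip_duration_s = 30, spontaneous_duration_s = 300) {
  blocks <- list()
  t0 <- 0
  specs <- list(
    list("drifting_gratings", dg_repeats),
    list("static_gratings", sg_repeats),
    list("natural_scenes", ns_repeats),
    list("natural_movie", nm_repeats)
  )
  for (i in seq_along(specs)) {
    b <- make_stimulus_table(specs[[i]][[1]], repeats = specs[[i]][[2]],
                             seed = child_seed(seed, i), start_s = t0,
                             clip_duration_s = clip_duration_s)
    t0 <- max(b$stop_s) + if (specs[[i]][[1]] == "drifting_gratings") 1 else 0
    blocks[[i]] <- b
  }
  blocks[[length(blocks) + 1]] <-
    make_stimulus_table("spontaneous", start_s = t0,
                        spontaneous_duration_s = spontaneous_duration_s)
  all_cols <- Reduce(union, lapply(blocks, names))
  blocks <- lapply(blocks, function(b) {
    for (cc in setdiff(all_cols, names(b))) b[[cc]] <- NA
    b[, all_cols, drop = FALSE]
  })
  out <- do.call(rbind, blocks)
  out$trial_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @rdname make_session
#' @param session a session table.
#' @return `session_duration`: total session length in seconds.
#' @export
session_duration <- function(session) max(session$stop_s)

spontaneous_epoch <- function(session) {
  sp <- session[session$stimulus_type == "spontaneous", , drop = FALSE]
  if (nrow(sp) == 0) {
    abort_calspike("session has no spontaneous epoch",
                   "calspike_no_spontaneous")
  }
  c(start_s = sp$start_s[1], stop_s = sp$stop_s[1])
}
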