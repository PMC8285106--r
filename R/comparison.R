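# Jensen-Shannon divergence (log base 2) between two probability vectors.
js_divergence_probs <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Jensen-Shannon distance between probability vectors
#'
#' @param p,q probability vectors on the same support (normalized
#'   internally).
#' @return `sqrt` of the Jensen-Shannon divergence with log base 2, so the
#'   distance lies in \[0, 1\].
#' @export
js_distance_probs <- function(p, q) {
  sqrt(max(js_divergence_probs(p, q), 0))
}

hist_unit_interval <- function(x, n_bins) {
  x <- x[!is.na(x)]
  if (any(x < -1e-9 | x > 1 + 1e-9)) {
    abort_calspike("continuous metric values must lie in [0, 1]",
                   "calspike_out_of_range")
  }
  x <- pmin(pmax(x, 0), 1)
  idx <- pmin(floor(x * n_bins) + 1L, n_bins)  # 1.0 goes to the top bin
  tabulate(idx, n_bins)
}

#' Jensen-Shannon distance between two metric samples
#'
#' Continuous metrics are histogrammed with `n_bins` equal bins on
#' \[0, 1\] (both endpoints included, 1.0 in the top bin); categorical
#' metrics (factors/characters, e.g. preferred conditions) get one bin per
#' condition over the union of levels. The distance is the square root of
#' the Jensen-Shannon divergence with log base 2, giving range \[0, 1\]:
#' 0 for identical histograms, 1 for disjoint supports.
#'
#' @param dist_a,dist_b non-empty samples (numeric in \[0,1\], or
#'   character/factor).
#' @param n_bins histogram bins for continuous metrics (default 10).
#' @return an object of class `comparison_result`: list with
#'   `js_distance`, `n_bins`, `n_a`, `n_b`, `hist_a`, `hist_b`.
#' @export
js_distance <- function(dist_a, dist_b, n_bins = 10) {
  if (length(dist_a) == 0 || length(dist_b) == 0) {
    abort_calspike("empty metric distribution", "calspike_empty_distribution")
  }
  categorical <- is.character(dist_a) || is.factor(dist_a)
  if (categorical) {
    lev <- sort(unique(c(as.character(dist_a), as.character(dist_b))))
    ha <- table(factor(as.character(dist_a), levels = lev))
    hb <- table(factor(as.character(dist_b), levels = lev))
    n_bins <- length(lev)
  } else {
    ha <- hist_unit_interval(dist_a, n_bins)
    hb <- hist_unit_interval(dist_b, n_bins)
  }
  structure(list(js_distance = js_distance_probs(as.numeric(ha), as.numeric(hb)),
                 n_bins = n_bins,
                 n_a = length(dist_a), n_b = length(dist_b),
                 hist_a = as.numeric(ha) / sum(ha),
                 hist_b = as.numeric(hb) / sum(hb)),
            class = "comparison_result")
}

#' Bootstrap p-value for a Jensen-Shannon distance
#'
#' The observed distance `D*` between the two modalities is compared to a
#' null of intra-modality distances: on each of `n_rep` repetitions two
#' disjoint subsamples (each of size `min(floor(n_a/2), n_b)`) are drawn
#' from `dist_a` and their distance computed. The p-value is
#' `(#{intra >= D*} + 1) / (n_rep + 1)`, so it is never exactly zero; zero
#' exceedances are rendered as `p < 1/(n_rep+1)` (e.g. "p < 0.001").
#'
#' @param dist_a,dist_b metric samples (subsampling draws from `dist_a`).
#' @param n_rep bootstrap repetitions (default 1000).
#' @param seed reproducibility seed.
#' @param n_bins histogram bins (continuous metrics).
#' @return a list with `p`, `p_text`, `observed` (`D*`), `null_distances`,
#'   `n_exceed`, and `subsample_size`.
#' @export
bootstrap_p <- function(dist_a, dist_b, n_rep = 1000, seed = 1, n_bins = 10) {
  m <- min(floor(length(dist_a) / 2), length(dist_b))
  if (m < 1) {
    abort_calspike("dist_a too small to yield two disjoint subsamples",
                   "calspike_insufficient_samples")
  }
  d_star <- js_distance(dist_a, dist_b, n_bins)$js_distance
  nulls <- with_seed(seed, vapply(seq_len(n_rep), function(i) {
    idx <- sample.int(length(dist_a), 2 * m)
    js_distance(dist_a[idx[seq_len(m)]], dist_a[idx[m + seq_len(m)]],
                n_bins)$js_distance
  }, numeric(1)))
  n_exceed <- sum(nulls >= d_star)
  p <- (n_exceed + 1) / (n_rep + 1)
  p_text <- if (n_exceed == 0) {
    sprintf("p < %.3g", signif(1 / (n_rep + 1), 1))
  } else sprintf("p = %.3g", p)
  list(p = p, p_text = p_text, observed = d_star, null_distances = nulls,
       n_exceed = n_exceed, subsample_size = m)
}

#' Quantile sub-selection sweep
#'
#' Recomputes the responsive fraction and the Jensen-Shannon distance to a
#' reference distribution while retaining only the upper (e.g. event rate)
#' or lower (e.g. ISI violations score) quantile of a filter variable, for
#' each value of an included-percent grid.
#'
#' @param metrics a per-unit `data.frame` with logical `responsive`, the
#'   metric column `value_field`, and the filter column `filter_field`.
#' @param filter_field name of the filter column.
#' @param direction `"high"` keeps the largest filter values, `"low"` the
#'   smallest.
#' @param grid included-percent grid (default 100 down to 10).
#' @param value_field metric column compared to the reference (values in
#'   \[0, 1\]; `NA`s dropped).
#' @param reference reference metric sample (the other modality).
#' @param n_bins histogram bins.
#' @return a `data.frame`: `included_percent`, `n_kept`,
#'   `responsive_fraction`, `js_distance`.
#' @export
quantile_sweep <- function(metrics, filter_field, direction = c("high", "low"),
                           grid = seq(100, 10, by = -10), value_field,
                           reference, n_bins = 10) {
  direction <- match.arg(direction)
  stopifnot(filter_field %in% names(metrics))
  fv <- metrics[[filter_field]]
  rows <- lapply(grid, function(pct) {
    q <- pct / 100
    keep <- if (direction == "high") {
      fv >= quantile(fv, 1 - q, type = 1)
    } else {
      fv <= quantile(fv, q, type = 1)
    }
    sub <- metrics[keep, , drop = FALSE]
    vals <- sub[[value_field]]
    vals <- vals[!is.na(vals)]
    js <- if (length(vals)) js_distance(vals, reference, n_bins)$js_distance
          else NA_real_
    data.frame(included_percent = pct, n_kept = nrow(sub),
               responsive_fraction = mean(sub$responsive),
               js_distance = js)
  })
  do.call(rbind, rows)
}

#' Match imaging laminar composition to ephys
#'
#' Removes layer 6 from consideration, keeps all imaging L5 units, and
#' randomly sub-samples imaging L2/3 and L4 so the imaging L2/3:L5 and
#' L4:L5 ratios equal the ephys ratios (ephys has the largest L5
#' fraction, so matching is a pure down-sampling of the imaging set).
#'
#' @param imaging_units,ephys_units `data.frame`s with a `layer` column
#'   (levels `L2/3`, `L4`, `L5`, `L6`).
#' @param seed reproducibility seed.
#' @return the sub-sampled imaging `data.frame` (no L6).
#' @export
match_layers <- function(imaging_units, ephys_units, seed = 1) {
  img <- imaging_units[imaging_units$layer != "L6", , drop = FALSE]
  eph <- ephys_units[ephys_units$layer != "L6", , drop = FALSE]
  n_e <- table(factor(eph$layer, levels = c("L2/3", "L4", "L5")))
  n_i <- table(factor(img$layer, levels = c("L2/3", "L4", "L5")))
  if (n_i[["L5"]] == 0 || n_e[["L5"]] == 0) {
    abort_calspike("L5 units required in both datasets", "calspike_no_l5")
  }
  keep_idx <- which(img$layer == "L5")
  with_seed(seed, {
    for (ly in c("L2/3", "L4")) {
      target <- round(n_e[[ly]] / n_e[["L5"]] * n_i[["L5"]])
      avail <- which(img$layer == ly)
      if (target > length(avail)) {
        abort_calspike(sprintf(
          "cannot match layer %s: would need %d of %d imaging units",
          ly, target, length(avail)), "calspike_unattainable_ratio")
      }
      keep_idx <- c(keep_idx, sample(avail, target))
    }
  })
  img[sort(keep_idx), , drop = FALSE]
}

#' Match the running-fraction distribution of imaging experiments to ephys
#'
#' Histogram-matches (rejection sampling over `n_bins` bins on \[0, 1\])
#' the per-experiment running fractions of the imaging dataset to the
#' ephys distribution. Bins occupied in ephys but empty in imaging are
#' skipped with a warning.
#'
#' @param imaging_rf,ephys_rf per-experiment running fractions in \[0, 1\].
#' @param n_bins histogram bins (default 10, i.e. deciles).
#' @param seed reproducibility seed.
#' @return integer indices of the retained imaging experiments.
#' @export
match_running_fraction <- function(imaging_rf, ephys_rf, n_bins = 10,
                                   seed = 1) {
  bin_of <- function(x) pmin(floor(pmin(pmax(x, 0), 1) * n_bins) + 1L, n_bins)
  bi <- bin_of(imaging_rf); be <- bin_of(ephys_rf)
  p_e <- tabulate(be, n_bins) / length(ephys_rf)
  p_i <- tabulate(bi, n_bins) / length(imaging_rf)
  missing_bins <- which(p_e > 0 & p_i == 0)
  if (length(missing_bins)) {
    warning(sprintf("no imaging experiments in %d ephys-occupied bin(s); skipped",
                    length(missing_bins)))
  }
  ratio <- ifelse(p_i > 0, p_e / p_i, 0)
  if (max(ratio) == 0) return(integer(0))
  accept <- ratio / max(ratio)
  keep <- with_seed(seed, runif(length(imaging_rf)) < accept[bi])
  which(keep)
}
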