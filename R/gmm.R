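# Full-covariance Gaussian mixture fitted by EM. Written in-package because
# no mixture-model package is assumed; d is small (4) so dense Cholesky
# algebra per component is cheap.

log_dmvnorm <- function(X, mean, cov) {
  d <- ncol(X)
  ch <- chol(cov)
  z <- forwardsolve(t(ch), t(X) - mean)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(z^2))
}

log_sum_exp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

gmm_loglik_matrix <- function(model, X) {
  k <- length(model$weights)
  L <- matrix(0, nrow(X), k)
  for (j in seq_len(k)) {
    L[, j] <- log(model$weights[j]) +
      log_dmvnorm(X, model$means[j, ], model$covs[, , j])
  }
  L
}

#' Fit a Gaussian mixture model by EM
#'
#' Full covariance per component; k-means initialization; covariances are
#' regularized by `reg_covar` on the diagonal. Degenerate fits (components
#' losing all support) raise an error so model-selection loops can skip
#' the offending k.
#'
#' @param X numeric matrix (rows = observations).
#' @param k number of components.
#' @param seed reproducibility seed (initialization).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param reg_covar diagonal covariance regularizer.
#' @return an object of class `gmm_model`: `weights`, `means`, `covs`,
#'   `loglik`, `k`, `d`.
#' @export
gmm_fit <- function(X, k, seed = 1, max_iter = 200, tol = 1e-6,
                    reg_covar = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < k) {
    abort_calspike("fewer observations than components", "calspike_gmm_small_n")
  }
  with_seed(seed, {
    centers <- if (k == 1) {
      matrix(colMeans(X), 1)
    } else {
      km <- suppressWarnings(kmeans(X, k, nstart = 3, iter.max = 50))
      km$centers
    }
    weights <- rep(1 / k, k)
    covs <- array(0, c(d, d, k))
    base_cov <- cov(X) + diag(reg_covar, d)
    for (j in seq_len(k)) covs[, , j] <- base_cov
    model <- list(weights = weights, means = centers, covs = covs,
                  k = k, d = d)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      L <- gmm_loglik_matrix(model, X)
      lse <- log_sum_exp_rows(L)
      ll <- sum(lse)
      R <- exp(L - lse)
      nk <- colSums(R)
      if (any(nk < 1e-8)) {
        abort_calspike("degenerate component (no support)",
                       "calspike_gmm_degenerate")
      }
      model$weights <- nk / n
      model$means <- t(vapply(seq_len(k), function(j) {
        colSums(R[, j] * X) / nk[j]
      }, numeric(d)))
      for (j in seq_len(k)) {
        Xc <- sweep(X, 2, model$means[j, ])
        model$covs[, , j] <- crossprod(Xc * sqrt(R[, j])) / nk[j] +
          diag(reg_covar, d)
      }
      if (abs(ll - ll_old) < tol * abs(ll)) break
      ll_old <- ll
    }
    model$loglik <- ll
    structure(model, class = "gmm_model")
  })
}

#' @rdname gmm_fit
#' @param model a fitted `gmm_model`.
#' @return `gmm_loglik`: total log-likelihood of `X` under `model`.
#' @export
gmm_loglik <- function(model, X) {
  sum(log_sum_exp_rows(gmm_loglik_matrix(model, as.matrix(X))))
}

gmm_n_params <- function(k, d) (k - 1) + k * d + k * d * (d + 1) / 2

#' Select a mixture order by cross-validated held-out BIC
#'
#' For each k in `k_range`, fits the model on the training folds and
#' scores `-2 * loglik(held-out) + p * log(n_held-out)` (p = number of
#' free parameters), averaged over `n_folds` folds; the k minimizing the
#' average held-out BIC is refit on all data. Values of k whose fits fail
#' (singular/degenerate) are skipped with a warning.
#'
#' @param X reliability matrix (rows = units, columns = stimulus types).
#' @param k_range candidate component counts (default 1..50).
#' @param n_folds cross-validation folds (default 4).
#' @param seed reproducibility seed.
#' @return a list with `model` (the refit `gmm_model`), `k`, and
#'   `bic_table` (`data.frame` of k and mean held-out BIC).
#' @export
fit_and_select_gmm <- function(X, k_range = 1:50, n_folds = 4, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- with_seed(child_seed(seed, 0),
                     sample(rep_len(seq_len(n_folds), n)))
  scores <- vapply(k_range, function(k) {
    if (n - ceiling(n / n_folds) < k) return(NA_real_)  # k > training size
    bics <- rep(NA_real_, n_folds)
    for (f in seq_len(n_folds)) {
      tr <- X[folds != f, , drop = FALSE]
      te <- X[folds == f, , drop = FALSE]
      fit <- tryCatch(gmm_fit(tr, k, seed = child_seed(seed, k * 131 + f)),
                      error = function(e) NULL)
      if (is.null(fit)) next
      ll <- tryCatch(gmm_loglik(fit, te), error = function(e) NA_real_)
      bics[f] <- -2 * ll + gmm_n_params(k, ncol(X)) * log(nrow(te))
    }
    if (all(is.na(bics))) NA_real_ else mean(bics, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(scores))) {
    abort_calspike("no mixture order could be fit", "calspike_gmm_failed")
  }
  if (any(is.na(scores))) {
    warning(sprintf("%d value(s) of k skipped (singular or undersized fits)",
                    sum(is.na(scores))))
  }
  best_k <- k_range[which.min(scores)]
  model <- gmm_fit(X, best_k, seed = child_seed(seed, 999983))
  list(model = model, k = best_k,
       bic_table = data.frame(k = k_range, heldout_bic = scores))
}

canonical_stims <- c("drifting_gratings", "static_gratings",
                     "natural_scenes", "natural_movie")

#' Build an N x 4 reliability matrix from a metric table
#'
#' Pivots a [population_metrics()] table to one row per unit and one
#' column per canonical stimulus type, on the fractional scale (reliability
#' / 100). When several movie blocks are present their reliabilities are
#' combined by taking the maximum. Units missing a stimulus type get 0.
#'
#' @param metrics a `data.frame` with `unit_id`, `stimulus_type`,
#'   `response_reliability` (percent).
#' @return a numeric matrix with rownames = unit ids and columns in
#'   canonical stimulus order; entries in \[0, 1\].
#' @export
reliability_matrix <- function(metrics) {
  ids <- unique(metrics$unit_id)
  M <- matrix(0, length(ids), length(canonical_stims),
              dimnames = list(ids, canonical_stims))
  for (i in seq_along(ids)) {
    sub <- metrics[metrics$unit_id == ids[i], , drop = FALSE]
    for (stim in canonical_stims) {
      vals <- sub$response_reliability[sub$stimulus_type == stim]
      if (length(vals)) M[i, stim] <- max(vals) / 100
    }
  }
  M
}

class_label <- function(bits, stim_names) {
  if (!any(bits)) "none" else paste(stim_names[bits], collapse = "+")
}

#' All 16 canonical class labels
#'
#' Bit-patterns over (drifting gratings, static gratings, natural scenes,
#' natural movie) in canonical order.
#'
#' @param stim_names stimulus names (default the four canonical ones).
#' @return character vector of 16 labels ("none" first).
#' @export
all_class_labels <- function(stim_names = canonical_stims) {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(stim_names)))
  apply(as.matrix(grid), 1, function(b) class_label(b, stim_names))
}

#' Assign functional classes from a fitted mixture
#'
#' Each unit goes to its most probable cluster; each cluster is labeled by
#' the stimulus types for which the mean reliability of its members
#' exceeds `threshold` (fractional scale), yielding one of the 16
#' bit-pattern classes over the four stimulus types.
#'
#' @param model a fitted `gmm_model`.
#' @param X the reliability matrix used for prediction (fractions in
#'   \[0, 1\], columns in canonical stimulus order).
#' @param threshold responsiveness threshold on mean reliability
#'   (default 0.25).
#' @param stim_names column names (default canonical four).
#' @return an object of class `class_assignment`: `cluster` (per unit),
#'   `class` (per unit), `cluster_means`, `cluster_class`, and `fractions`
#'   (named vector over all 16 classes, summing to 1).
#' @export
assign_classes <- function(model, X, threshold = 0.25,
                           stim_names = canonical_stims) {
  X <- as.matrix(X)
  L <- gmm_loglik_matrix(model, X)
  cl <- max.col(L, ties.method = "first")
  k <- model$k
  cluster_means <- t(vapply(seq_len(k), function(j) {
    members <- cl == j
    if (any(members)) colMeans(X[members, , drop = FALSE]) else model$means[j, ]
  }, numeric(ncol(X))))
  cluster_class <- apply(cluster_means > threshold, 1, class_label,
                         stim_names = stim_names)
  unit_class <- cluster_class[cl]
  labels <- all_class_labels(stim_names)
  fractions <- as.numeric(table(factor(unit_class, levels = labels))) /
    length(unit_class)
  names(fractions) <- labels
  structure(list(cluster = cl, class = unit_class,
                 cluster_means = cluster_means,
                 cluster_class = cluster_class,
                 fractions = fractions, threshold = threshold),
            class = "class_assignment")
}

#' Cross-modality class-fraction analysis with a threshold sweep
#'
#' Repeats the fit-and-assign pipeline `n_repeats` times with fresh seeds
#' on both reliability matrices. Side B is always thresholded at
#' `threshold_b`; side A is swept over `threshold_grid`, and for each
#' threshold the Jensen-Shannon distance between the two 16-class
#' fraction distributions is computed (mean over repeats). Reports the
#' minimizing threshold and the class fractions (mean and SD across
#' repeats) for both sides.
#'
#' @param reliability_a,reliability_b reliability matrices (fractions).
#' @param threshold_grid thresholds swept on side A.
#' @param n_repeats clustering repeats (default 100; scale down for quick
#'   runs).
#' @param threshold_b fixed threshold for side B (default 0.25).
#' @param k_range,n_folds passed to [fit_and_select_gmm()].
#' @param seed reproducibility seed.
#' @return a list with `jsd_curve` (`data.frame` threshold/mean/sd),
#'   `best_threshold`, `fractions_a` (at `best_threshold`), `fractions_b`,
#'   each a list of `mean` and `sd` vectors over the 16 classes.
#' @export
class_fraction_analysis <- function(reliability_a, reliability_b,
                                    threshold_grid = seq(0.1, 0.6, by = 0.05),
                                    n_repeats = 100, threshold_b = 0.25,
                                    k_range = 1:50, n_folds = 4, seed = 1) {
  labels <- all_class_labels()
  jsd <- matrix(NA_real_, n_repeats, length(threshold_grid))
  fr_a <- array(NA_real_, c(n_repeats, length(threshold_grid), length(labels)))
  fr_b <- matrix(NA_real_, n_repeats, length(labels))
  for (r in seq_len(n_repeats)) {
    sa <- child_seed(seed, 2 * r)
    sb <- child_seed(seed, 2 * r + 1)
    fit_a <- fit_and_select_gmm(reliability_a, k_range, n_folds, seed = sa)
    fit_b <- fit_and_select_gmm(reliability_b, k_range, n_folds, seed = sb)
    f_b <- assign_classes(fit_b$model, reliability_b, threshold_b)$fractions
    fr_b[r, ] <- f_b
    for (ti in seq_along(threshold_grid)) {
      f_a <- assign_classes(fit_a$model, reliability_a,
                            threshold_grid[ti])$fractions
      fr_a[r, ti, ] <- f_a
      # smooth zero cells so the distance stays finite on disjoint classes
      jsd[r, ti] <- js_distance_probs(f_a + 1e-12, f_b + 1e-12)
    }
  }
  curve <- data.frame(threshold = threshold_grid,
                      jsd_mean = colMeans(jsd),
                      jsd_sd = apply(jsd, 2, sd))
  best_i <- which.min(curve$jsd_mean)
  mk <- function(M) {
    M <- matrix(M, ncol = length(labels))
    list(mean = setNames(colMeans(M), labels),
         sd = setNames(apply(M, 2, sd), labels))
  }
  list(jsd_curve = curve,
       best_threshold = threshold_grid[best_i],
       fractions_a = mk(fr_a[, best_i, ]),
       fractions_b = mk(fr_b))
}
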