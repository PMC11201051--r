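#' Presence-background AUC
#'
#' The pairwise concordance statistic: the mean over all (presence,
#' background) score pairs of 1 if the presence scores higher, 0.5 on a
#' tie, 0 otherwise — computed via midranks (Mann-Whitney), which is
#' identical to the brute-force pair count and invariant under strictly
#' monotone transforms of all scores.
#'
#' @param presence_scores,background_scores Non-empty numeric score
#'   vectors.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (np == 0 || nb == 0) stop("auc: empty score set")
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Grade an AUC value on the conventional predictive-quality bands
#'
#' Bands are half-open `[lo, hi)` with the top band closed at 1:
#' 0.1-0.6 "failure", 0.6-0.7 "poor", 0.7-0.8 "average", 0.8-0.9 "good",
#' 0.9-1.0 "excellent"; values below 0.1 are "below scale".
#'
#' @param auc_value AUC in \[0, 1\] (vectorised).
#' @return Character grade label(s).
#' @export
auc_grade <- function(auc_value) {
  stopifnot(all(auc_value >= 0 & auc_value <= 1))
  cut_pts <- c(0, 0.1, 0.6, 0.7, 0.8, 0.9, 1 + 1e-9)
  labs <- c("below scale", "failure", "poor", "average", "good", "excellent")
  labs[findInterval(auc_value, cut_pts, rightmost.closed = FALSE)]
}

#' Deterministic train/test split of an occurrence set
#'
#' Test size is `floor(test_fraction * n)` (the remainder trains); the
#' split is a deterministic function of `(seed, replicate)`.
#'
#' @param occ An `occurrence_set` (or data frame).
#' @param test_fraction Proportion held out (default 0.25).
#' @param seed Master seed.
#' @param replicate Replicate index (>= 1).
#' @return List with `train` and `test` subsets (input order preserved
#'   within each).
#' @export
split_occurrences <- function(occ, test_fraction = 0.25, seed = 1,
                              replicate = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1, replicate >= 1)
  n <- nrow(occ)
  if (is.null(n) || n < 4) stop("split_occurrences: need at least 4 records")
  n_test <- floor(test_fraction * n)
  if (n_test < 1) stop("split_occurrences: test fraction yields empty test set")
  idx <- with_seed(stage_seed(seed, replicate), sample.int(n, n_test))
  test_mask <- logical(n); test_mask[idx] <- TRUE
  list(train = occ[!test_mask, , drop = FALSE],
       test = occ[test_mask, , drop = FALSE])
}

#' Replicate train/test evaluation of the maximum-entropy model
#'
#' Repeatedly splits the presences ([split_occurrences()]), fits the model
#' on each training set, and scores the held-out presences against the
#' background sample (re-used across replicates, as are the feature
#' definitions and scaling, which depend only on the background). Reports
#' per-replicate test AUCs, their mean and grade, and the cell-wise mean
#' logistic suitability map across replicates — the map used by the
#' downstream classification and range-change steps.
#'
#' @param stack A [grid_stack()].
#' @param occ An `occurrence_set` of presences.
#' @param config A [maxent_config()].
#' @param test_fraction Held-out proportion per replicate (default 0.25).
#' @param replicates Number of replicates (default 100).
#' @param seed Master seed for the splits (defaults to `config$seed`).
#' @param keep_models Store each replicate's lambda vector (needed to
#'   project replicate-mean maps onto other scenarios).
#' @return An object of class `maxent_eval`: `aucs`, `mean_auc`, `grade`,
#'   `mean_map` (an [env_grid()]), `models` (if kept), and the shared
#'   feature/background state.
#' @export
evaluate_replicates <- function(stack, occ, config = maxent_config(),
                                test_fraction = 0.25, replicates = 100,
                                seed = config$seed, keep_models = TRUE) {
  stopifnot(replicates >= 1)
  feats <- build_features(stack, occ, config)
  sv <- stack_values(stack)
  cell_scaled <- scale_values(sv$values, feats$scaling)
  cell_F <- feature_matrix(cell_scaled, feats$defs)
  n_cells <- nrow(cell_F)
  mean_p <- numeric(n_cells)
  aucs <- numeric(replicates)
  models <- if (keep_models) vector("list", replicates) else NULL
  n <- nrow(feats$presence)
  for (i in seq_len(replicates)) {
    n_test <- floor(test_fraction * n)
    if (n_test < 1 || n < 4) stop("evaluate_replicates: too few presences")
    idx <- with_seed(stage_seed(seed, i), sample.int(n, n_test))
    train_F <- feats$presence[-idx, , drop = FALSE]
    test_F <- feats$presence[idx, , drop = FALSE]
    fit <- fit_maxent(train_F, feats$background, config, defs = feats$defs)
    test_s <- as.numeric(test_F %*% fit$lambdas)
    bg_s <- as.numeric(feats$background %*% fit$lambdas)
    aucs[i] <- auc(test_s, bg_s)
    link <- as.numeric(cell_F %*% fit$lambdas)
    q <- exp(link - fit$log_partition)
    mean_p <- mean_p + logistic_from_raw(q, fit$entropy)
    if (keep_models)
      models[[i]] <- list(lambdas = fit$lambdas,
                          log_partition = fit$log_partition,
                          entropy = fit$entropy)
  }
  mean_p <- mean_p / replicates
  out <- matrix(NA_real_, stack$header$nrows, stack$header$ncols)
  out[sv$cells] <- mean_p
  mean_map <- env_grid(out, stack$header$xllcorner, stack$header$yllcorner,
                       stack$header$cellsize, stack$header$nodata_value,
                       name = "mean_suitability")
  structure(list(aucs = aucs, mean_auc = mean(aucs),
                 grade = auc_grade(mean(aucs)), mean_map = mean_map,
                 models = models, features = feats,
                 replicates = replicates, seed = seed,
                 test_fraction = test_fraction, config = config),
            class = "maxent_eval")
}

#' @export
print.maxent_eval <- function(x, ...) {
  cat(sprintf("<maxent_eval> %d replicate(s); mean test AUC %.3f (%s), range [%.3f, %.3f]\n",
              x$replicates, x$mean_auc, x$grade, min(x$aucs), max(x$aucs)))
  invisible(x)
}

#' Mean projection of replicate models onto a scenario stack
#'
#' Projects every replicate model from [evaluate_replicates()] (run with
#' `keep_models = TRUE`) onto `stack`, with clamping to the training range,
#' and averages the logistic maps cell-wise.
#'
#' @param eval_result A `maxent_eval` with stored models.
#' @param stack Target [grid_stack()] (must contain all model variables).
#' @return An [env_grid()] of mean logistic suitability.
#' @export
project_mean <- function(eval_result, stack) {
  if (is.null(eval_result$models))
    stop("project_mean: evaluate_replicates() was run with keep_models = FALSE")
  feats <- eval_result$features
  sv <- stack_values(stack)
  vars <- feats$var_names
  missing <- setdiff(vars, colnames(sv$values))
  if (length(missing))
    stop("project_mean: variable(s) missing from stack: ",
         paste(missing, collapse = ", "))
  scaled <- scale_values(sv$values[, vars, drop = FALSE], feats$scaling,
                         clamp = TRUE)
  F <- feature_matrix(scaled, feats$defs)
  acc <- numeric(nrow(F))
  for (m in eval_result$models) {
    q <- exp(as.numeric(F %*% m$lambdas) - m$log_partition)
    acc <- acc + logistic_from_raw(q, m$entropy)
  }
  acc <- acc / length(eval_result$models)
  out <- matrix(NA_real_, stack$header$nrows, stack$header$ncols)
  out[sv$cells] <- acc
  env_grid(out, stack$header$xllcorner, stack$header$yllcorner,
           stack$header$cellsize, stack$header$nodata_value,
           name = "mean_suitability")
}
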