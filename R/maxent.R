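## Maximum-entropy (Gibbs) niche model over background cells.
##
## Model: raw distribution q(x) = exp(sum_j lambda_j f_j(x)) / Z with Z
## summed over the background sample.  Fitting maximises the regularised
## training gain
##     G(lambda) = mean_presence log q  + log n_bg  - sum_j beta_j |lambda_j|
## (the first two terms are the gain relative to the uniform baseline, so
## G(0) = 0) by cyclic coordinate descent: per coordinate a damped Newton
## step with L1 soft-thresholding, accepted only if the exact objective
## does not decrease, which keeps the gain trace non-decreasing and makes
## per-variable gain crediting well defined.

BETA_CLASS <- c(linear = 0.05, quadratic = 0.05, product = 0.05,
                forward_hinge = 0.5, reverse_hinge = 0.5, threshold = 1.0)

#' Training configuration for the maximum-entropy model
#'
#' @param reg_multiplier Global multiplier on the per-feature L1 penalties
#'   (default 1; 0 disables regularisation).
#' @param background_size Number of background cells sampled uniformly
#'   without replacement from the stack mask (all cells if the mask is
#'   smaller).
#' @param max_iterations Maximum full coordinate-descent cycles.
#' @param tolerance Convergence threshold on the relative gain change per
#'   cycle.
#' @param hinge_knots Hinge/threshold knots per variable, placed at equally
#'   spaced interior quantiles of the scaled background values.
#' @param seed Seed for background sampling (and any other fit randomness).
#' @param feature_classes Feature expansion to use; any subset of
#'   `"linear"`, `"quadratic"`, `"product"`, `"forward_hinge"`,
#'   `"reverse_hinge"`, `"threshold"`.
#' @return A list of class `maxent_config`.
#' @export
maxent_config <- function(reg_multiplier = 1.0, background_size = 10000,
                          max_iterations = 500, tolerance = 1e-5,
                          hinge_knots = 10, seed = 1,
                          feature_classes = c("linear", "quadratic", "product",
                                              "forward_hinge", "reverse_hinge")) {
  stopifnot(reg_multiplier >= 0, background_size >= 1, max_iterations >= 1,
            tolerance > 0, hinge_knots >= 1,
            all(feature_classes %in% names(BETA_CLASS)))
  structure(list(reg_multiplier = reg_multiplier,
                 background_size = as.integer(background_size),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, hinge_knots = as.integer(hinge_knots),
                 seed = seed, feature_classes = feature_classes),
            class = "maxent_config")
}

## ---- feature machinery -----------------------------------------------

## scale raw variable matrix to [0,1] using per-variable (min, max);
## constant variables map to 0.5.  Clamps outside the training range.
scale_values <- function(X, scaling, clamp = TRUE) {
  X <- as.matrix(X)
  S <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  for (v in colnames(X)) {
    lo <- scaling[[v]][1]; hi <- scaling[[v]][2]
    if (hi - lo <= 0) { S[, v] <- 0.5; next }
    x <- X[, v]
    if (clamp) x <- pmin(hi, pmax(lo, x))
    S[, v] <- (x - lo) / (hi - lo)
  }
  S
}

## defs: data.frame(kind, var, var2, knot, name)
make_feature_defs <- function(bg_scaled, config) {
  vars <- colnames(bg_scaled)
  classes <- config$feature_classes
  const <- apply(bg_scaled, 2, function(x) max(x) - min(x) < 1e-12)
  defs <- data.frame(kind = character(), var = character(),
                     var2 = character(), knot = numeric(),
                     name = character(), stringsAsFactors = FALSE)
  add <- function(kind, var, var2 = NA_character_, knot = NA_real_) {
    nm <- switch(kind,
      linear = paste0("lin(", var, ")"),
      quadratic = paste0("quad(", var, ")"),
      product = paste0("prod(", var, ",", var2, ")"),
      forward_hinge = sprintf("fh(%s,%.4f)", var, knot),
      reverse_hinge = sprintf("rh(%s,%.4f)", var, knot),
      threshold = sprintf("thr(%s,%.4f)", var, knot))
    defs[nrow(defs) + 1L, ] <<- list(kind, var, var2, knot, nm)
  }
  for (v in vars) {
    add("linear", v)
    if (const[[v]]) next  # nonlinear features of a constant carry nothing
    if ("quadratic" %in% classes) add("quadratic", v)
    knots <- unique(unname(stats::quantile(
      bg_scaled[, v], probs = seq_len(config$hinge_knots) /
        (config$hinge_knots + 1), type = 7)))
    for (k in knots) {
      if ("forward_hinge" %in% classes && k < 1 - 1e-9) add("forward_hinge", v, knot = k)
      if ("reverse_hinge" %in% classes && k > 1e-9) add("reverse_hinge", v, knot = k)
      if ("threshold" %in% classes && k > 1e-9 && k < 1 - 1e-9) add("threshold", v, knot = k)
    }
  }
  if ("product" %in% classes && length(vars) >= 2) {
    for (i in seq_len(length(vars) - 1)) for (j in (i + 1):length(vars)) {
      if (!const[[vars[i]]] && !const[[vars[j]]]) add("product", vars[i], vars[j])
    }
  }
  defs
}

## evaluate features for a scaled value matrix
feature_matrix <- function(scaled, defs) {
  n <- nrow(scaled)
  F <- matrix(0, n, nrow(defs), dimnames = list(NULL, defs$name))
  for (j in seq_len(nrow(defs))) {
    x <- scaled[, defs$var[j]]
    F[, j] <- switch(defs$kind[j],
      linear = x,
      quadratic = x^2,
      product = x * scaled[, defs$var2[j]],
      forward_hinge = pmax(0, x - defs$knot[j]) / (1 - defs$knot[j]),
      reverse_hinge = pmax(0, defs$knot[j] - x) / defs$knot[j],
      threshold = as.numeric(x > defs$knot[j]))
  }
  F
}

#' Build feature matrices for presence and background points
#'
#' Variables are scaled per variable to \[0, 1\] using the background
#' min/max; the background is a uniform, seeded sample of the stack mask
#' (all valid cells when the mask is no larger than
#' `config$background_size`). Hinge/threshold knots sit at equally spaced
#' interior quantiles of the scaled background values. Nonlinear features
#' of a variable that is constant over the background are omitted (its
#' linear feature is kept); any remaining feature with zero variance on the
#' background is dropped.
#'
#' @param stack A [grid_stack()].
#' @param presence Either an `occurrence_set` (values are extracted with
#'   [extract_values()]; rejected points are dropped with a message) or a
#'   data frame / matrix of raw variable values at presence points.
#' @param config A [maxent_config()].
#' @return A list of class `maxent_features`: `defs`, `scaling`,
#'   `presence`/`background` feature matrices, the raw value tables
#'   `presence_values`/`background_values`, and `bg_cells`.
#' @export
build_features <- function(stack, presence, config = maxent_config()) {
  stopifnot(inherits(stack, "grid_stack"))
  vars <- names(stack$layers)
  if (inherits(presence, "occurrence_set") ||
      (is.data.frame(presence) && !all(vars %in% names(presence)))) {
    ex <- extract_values(stack, presence)
    if (nrow(ex$rejected))
      message("build_features: ", nrow(ex$rejected),
              " presence point(s) outside the grid/mask were dropped")
    pres_vals <- as.matrix(ex$values[, vars, drop = FALSE])
  } else {
    pres_vals <- as.matrix(presence[, vars, drop = FALSE])
  }
  if (nrow(pres_vals) < 2) stop("build_features: need at least 2 presences")

  all_cells <- which(stack$mask, arr.ind = TRUE)
  n_mask <- nrow(all_cells)
  bg_cells <- if (n_mask <= config$background_size) all_cells else
    with_seed(config$seed, all_cells[sample.int(n_mask, config$background_size), , drop = FALSE])
  bg_vals <- stack_values(stack, bg_cells)$values

  scaling <- lapply(vars, function(v) range(bg_vals[, v]))
  names(scaling) <- vars
  bg_scaled <- scale_values(bg_vals, scaling)
  pres_scaled <- scale_values(pres_vals, scaling)

  defs <- make_feature_defs(bg_scaled, config)
  Fb <- feature_matrix(bg_scaled, defs)
  keep <- defs$kind == "linear" |
    apply(Fb, 2, function(x) max(x) - min(x)) > 1e-12
  defs <- defs[keep, , drop = FALSE]
  Fb <- Fb[, keep, drop = FALSE]
  Fp <- feature_matrix(pres_scaled, defs)
  structure(list(defs = defs, scaling = scaling,
                 presence = Fp, background = Fb,
                 presence_values = pres_vals, background_values = bg_vals,
                 bg_cells = bg_cells, var_names = vars),
            class = "maxent_features")
}

## per-feature L1 penalties
feature_betas <- function(defs, bg_features, n_presence, reg_multiplier) {
  sds <- apply(bg_features, 2, stats::sd)
  unname(reg_multiplier * BETA_CLASS[defs$kind] * sds / sqrt(n_presence))
}

#' Fit a maximum-entropy model from feature matrices
#'
#' Low-level fitter; most users call [maxent()]. Maximises the regularised
#' training gain (mean presence log-density relative to uniform, minus the
#' L1 penalty) by cyclic coordinate descent with damped Newton steps and
#' soft-thresholding; every accepted step increases the exact objective,
#' so the gain trace is non-decreasing. At convergence the KKT box
#' condition holds: |E_q\[f_j\] - mean_presence\[f_j\]| <= beta_j for every
#' feature, with equality (up to tolerance) where lambda_j is active.
#'
#' @param presence,background Numeric feature matrices (points x features)
#'   with matching columns, or a `maxent_features` object as `presence`.
#' @param config A [maxent_config()].
#' @param defs Optional feature-definition table (supplied automatically
#'   when `presence` is a `maxent_features` object).
#' @param beta Optional per-feature penalty vector; by default computed as
#'   `reg_multiplier * beta_class * sd_background(f_j) / sqrt(n_presence)`
#'   with class constants 0.05 (linear/quadratic/product), 0.5 (hinge),
#'   1.0 (threshold).
#' @return An object of class `maxent`; see [maxent()].
#' @export
fit_maxent <- function(presence, background = NULL, config = maxent_config(),
                       defs = NULL, beta = NULL) {
  feats <- NULL
  if (inherits(presence, "maxent_features")) {
    feats <- presence
    background <- feats$background
    presence <- feats$presence
    defs <- feats$defs
  }
  P <- as.matrix(presence); B <- as.matrix(background)
  if (ncol(P) != ncol(B)) stop("fit_maxent: feature column mismatch")
  if (nrow(P) < 2) stop("fit_maxent: need at least 2 presences")
  if (!all(is.finite(P)) || !all(is.finite(B)))
    stop("fit_maxent: non-finite feature values")
  m <- nrow(P); n <- nrow(B); K <- ncol(P)
  if (is.null(defs))
    defs <- data.frame(kind = rep("linear", K), var = colnames(B),
                       var2 = NA_character_, knot = NA_real_,
                       name = colnames(B), stringsAsFactors = FALSE)
  if (is.null(beta)) beta <- feature_betas(defs, B, m, config$reg_multiplier)
  beta <- rep_len(beta, K)

  pj <- unname(colMeans(P))
  lambda <- numeric(K)
  s <- numeric(n)          # background scores
  q <- rep(1 / n, n)
  lin_term <- 0            # sum lambda_j * pj
  pen <- 0                 # sum beta_j |lambda_j|
  lme <- 0                 # log mean exp(s)
  gain <- 0
  trace <- vector("list", 2048L); n_tr <- 0L
  converged <- FALSE
  iter <- 0L

  for (cycle in seq_len(config$max_iterations)) {
    iter <- cycle
    gain_at_cycle_start <- gain
    for (j in seq_len(K)) {
      fj <- B[, j]
      Eq <- sum(q * fj)
      g1 <- pj[j] - Eq
      if (lambda[j] == 0 && abs(g1) <= beta[j] + 1e-12) next
      v <- sum(q * fj * fj) - Eq^2
      if (v < 1e-12) next
      zj <- lambda[j] * v + g1
      lam_new <- sign(zj) * max(0, abs(zj) - beta[j]) / v
      d <- lam_new - lambda[j]
      if (abs(d) < 1e-12) next
      d <- max(-10, min(10, d))
      accepted <- FALSE
      for (bt in 1:30) {
        s_try <- s + d * fj
        Mx <- max(s_try)
        w <- exp(s_try - Mx)
        sw <- sum(w)
        lme_try <- Mx + log(sw / n)
        lam_try <- lambda[j] + d
        lin_try <- lin_term + d * pj[j]
        pen_try <- pen - beta[j] * abs(lambda[j]) + beta[j] * abs(lam_try)
        gain_try <- lin_try - lme_try - pen_try
        if (gain_try >= gain - 1e-12) {
          delta <- max(0, gain_try - gain)
          lambda[j] <- lam_try; s <- s_try; q <- w / sw
          lin_term <- lin_try; pen <- pen_try; lme <- lme_try
          gain <- gain_try
          if (delta > 0) {
            n_tr <- n_tr + 1L
            if (n_tr > length(trace)) trace <- c(trace, vector("list", length(trace)))
            trace[[n_tr]] <- c(cycle, j, delta, gain)
          }
          accepted <- TRUE
          break
        }
        d <- d / 2
      }
    }
    if (gain - gain_at_cycle_start < config$tolerance * max(1, abs(gain))) {
      converged <- TRUE
      break
    }
  }

  Mx <- max(s)
  log_partition <- Mx + log(sum(exp(s - Mx)))
  H <- -sum(ifelse(q > 0, q * log(q), 0))
  tr <- if (n_tr) {
    tm <- do.call(rbind, trace[seq_len(n_tr)])
    data.frame(cycle = as.integer(tm[, 1]), feature = as.integer(tm[, 2]),
               name = defs$name[tm[, 2]], var = defs$var[tm[, 2]],
               var2 = defs$var2[tm[, 2]], delta = tm[, 3], gain = tm[, 4],
               stringsAsFactors = FALSE)
  } else {
    data.frame(cycle = integer(), feature = integer(), name = character(),
               var = character(), var2 = character(), delta = numeric(),
               gain = numeric(), stringsAsFactors = FALSE)
  }
  if (!converged)
    warning("fit_maxent: no convergence in ", config$max_iterations, " cycles")

  structure(list(
    defs = defs, lambdas = stats::setNames(lambda, defs$name), beta = beta,
    scaling = if (!is.null(feats)) feats$scaling else NULL,
    var_names = if (!is.null(feats)) feats$var_names else unique(defs$var),
    log_partition = log_partition, entropy = H, gain = gain,
    gain_trace = tr, converged = converged, iterations = iter,
    n_presence = m, n_background = n,
    presence_values = if (!is.null(feats)) feats$presence_values else NULL,
    background_values = if (!is.null(feats)) feats$background_values else NULL,
    bg_cells = if (!is.null(feats)) feats$bg_cells else NULL,
    bg_q = q, config = config), class = "maxent")
}

#' Fit a maximum-entropy niche model to occurrences and a raster stack
#'
#' The central fitting function of the package. Builds the feature
#' expansion over a seeded background sample of the stack ([build_features()])
#' and fits the L1-regularised Gibbs model ([fit_maxent()]).
#'
#' @param stack A [grid_stack()] of environmental layers.
#' @param occurrences An `occurrence_set` of presence points, or a table of
#'   raw variable values at presences.
#' @param config A [maxent_config()].
#' @return An object of class `maxent` with components including `lambdas`
#'   (fitted feature weights), `entropy` (entropy H of the fitted raw
#'   distribution over the background), `gain` (final regularised training
#'   gain), `gain_trace` (per accepted step: credited feature and gain
#'   increment), and the scaling/clamping ranges used for projection.
#'   Methods: [predict.maxent()], `print`, `summary`, `coef`, `plot`.
#' @seealso [percent_contribution()], [permutation_importance()],
#'   [jackknife_gains()], [response_curve()], [evaluate_replicates()]
#' @export
maxent <- function(stack, occurrences, config = maxent_config()) {
  feats <- build_features(stack, occurrences, config)
  model <- fit_maxent(feats, config = config)
  model$header <- stack$header
  model
}

#' @export
print.maxent <- function(x, ...) {
  cat(sprintf("<maxent> %d features over %d variables; %d presences, %d background cells\n",
              nrow(x$defs), length(x$var_names), x$n_presence, x$n_background))
  cat(sprintf("  regularised gain %.4f, entropy %.4f, %d active features, %s in %d cycles\n",
              x$gain, x$entropy, sum(x$lambdas != 0),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @export
coef.maxent <- function(object, ...) object$lambdas

#' @export
summary.maxent <- function(object, ...) {
  pc <- tryCatch(percent_contribution(object), error = function(e) NULL)
  out <- list(model = object, percent_contribution = pc)
  class(out) <- "summary.maxent"
  out
}

#' @export
print.summary.maxent <- function(x, ...) {
  print(x$model)
  if (!is.null(x$percent_contribution)) {
    cat("Percent contribution:\n")
    pc <- sort(x$percent_contribution, decreasing = TRUE)
    for (v in names(pc)) cat(sprintf("  %-12s %6.2f%%\n", v, pc[[v]]))
  }
  invisible(x)
}

#' @export
plot.maxent <- function(x, ...) {
  if (nrow(x$gain_trace) == 0) {
    warning("no accepted optimisation steps to plot")
    return(invisible(x))
  }
  graphics::plot(seq_len(nrow(x$gain_trace)), x$gain_trace$gain, type = "l",
                 xlab = "accepted step", ylab = "regularised gain",
                 main = "Training gain trace", ...)
  invisible(x)
}

## ---- prediction -------------------------------------------------------

## link scores (sum lambda f) for a raw variable value table
model_scores <- function(model, values, clamp = TRUE) {
  if (is.null(model$scaling))
    stop("model was fitted from bare feature matrices; supply features directly")
  vars <- model$var_names
  missing <- setdiff(vars, colnames(values))
  if (length(missing))
    stop("predict: variable(s) missing from newdata: ",
         paste(missing, collapse = ", "))
  scaled <- scale_values(values[, vars, drop = FALSE], model$scaling,
                         clamp = clamp)
  F <- feature_matrix(scaled, model$defs)
  as.numeric(F %*% model$lambdas)
}

logistic_from_raw <- function(q, H) {
  eq <- exp(H) * q
  eq / (1 + eq)
}

#' Predict suitability from a fitted maximum-entropy model
#'
#' For a [grid_stack()] `newdata`, returns an [env_grid()] of predictions
#' over the stack mask (nodata elsewhere); projection onto a new stack
#' clamps variable values to the training range by default. For a data
#' frame or matrix of raw variable values, returns a numeric vector. With
#' `newdata` missing, predicts on the training background, where
#' `type = "raw"` sums to 1.
#'
#' @param object A fitted [maxent()] model.
#' @param newdata A `grid_stack`, a table of raw variable values, or
#'   missing.
#' @param type `"logistic"` (default; suitability in (0,1) via
#'   `p = e^H q / (1 + e^H q)` with H the training entropy), `"raw"`
#'   (Gibbs density relative to the training partition function), or
#'   `"link"` (linear predictor).
#' @param clamp Clamp projection values to the training range (default
#'   `TRUE`).
#' @param ... Unused.
#' @return An `env_grid` or numeric vector, matching `newdata`.
#' @export
predict.maxent <- function(object, newdata = NULL,
                           type = c("logistic", "raw", "link"),
                           clamp = TRUE, ...) {
  type <- match.arg(type)
  finish <- function(link) {
    switch(type,
           link = link,
           raw = exp(link - object$log_partition),
           logistic = logistic_from_raw(exp(link - object$log_partition),
                                        object$entropy))
  }
  if (is.null(newdata)) {
    if (!is.null(object$background_values))
      return(finish(model_scores(object, object$background_values, clamp = FALSE)))
    # bare-matrix fit: the training-background raw distribution is stored
    return(switch(type,
                  raw = object$bg_q,
                  link = log(object$bg_q) + object$log_partition,
                  logistic = logistic_from_raw(object$bg_q, object$entropy)))
  }
  if (is.null(object$scaling) && (is.matrix(newdata) || is.data.frame(newdata))) {
    # fitted from bare feature matrices: newdata is a feature matrix
    nd <- as.matrix(newdata)
    if (ncol(nd) != length(object$lambdas))
      stop("predict: feature matrix has ", ncol(nd), " columns; model has ",
           length(object$lambdas), " features")
    return(finish(as.numeric(nd %*% object$lambdas)))
  }
  if (inherits(newdata, "grid_stack")) {
    sv <- stack_values(newdata)
    link <- model_scores(object, sv$values, clamp = clamp)
    out <- matrix(NA_real_, newdata$header$nrows, newdata$header$ncols)
    out[sv$cells] <- finish(link)
    return(env_grid(out, newdata$header$xllcorner, newdata$header$yllcorner,
                    newdata$header$cellsize, newdata$header$nodata_value,
                    name = paste0("suitability_", type)))
  }
  finish(model_scores(object, as.matrix(newdata), clamp = clamp))
}

#' Project a fitted model onto another (e.g. future-scenario) stack
#'
#' Convenience wrapper around [predict.maxent()] with logistic output and
#' clamping on; the classic transfer step across climate periods.
#'
#' @param model A fitted [maxent()] model.
#' @param stack A [grid_stack()] containing all model variables.
#' @param clamp Clamp values to the training range (default `TRUE`).
#' @return An [env_grid()] of logistic suitability.
#' @export
project_suitability <- function(model, stack, clamp = TRUE) {
  predict(model, newdata = stack, type = "logistic", clamp = clamp)
}

## ---- importance measures ---------------------------------------------

#' Percent contribution of each variable
#'
#' Credits every accepted coordinate-descent step's increase in regularised
#' gain to the stepped feature's variable (product features split 50/50
#' between their two variables), then rescales to percentages summing
#' to 100.
#'
#' @param model A fitted [maxent()] model.
#' @return Named numeric vector of percentages (one per model variable).
#' @export
percent_contribution <- function(model) {
  vars <- model$var_names
  credit <- stats::setNames(numeric(length(vars)), vars)
  tr <- model$gain_trace
  for (i in seq_len(nrow(tr))) {
    if (!is.na(tr$var2[i])) {
      credit[tr$var[i]] <- credit[tr$var[i]] + tr$delta[i] / 2
      credit[tr$var2[i]] <- credit[tr$var2[i]] + tr$delta[i] / 2
    } else {
      credit[tr$var[i]] <- credit[tr$var[i]] + tr$delta[i]
    }
  }
  total <- sum(credit)
  if (total <= 0) {
    warning("percent_contribution: zero total gain; contributions degenerate")
    return(credit)
  }
  100 * credit / total
}

#' Permutation importance of each variable
#'
#' For each variable, its raw values are permuted jointly across the
#' presence and background points, features are rebuilt, and the drop in
#' training presence-background AUC relative to the unpermuted model is
#' recorded; drops are floored at 0 and rescaled to sum to 100.
#'
#' @param model A fitted [maxent()] model (fitted via [maxent()] /
#'   [build_features()], so the raw value tables are stored).
#' @param seed Seed controlling the permutations.
#' @return Named numeric vector of percentages.
#' @export
permutation_importance <- function(model, seed = model$config$seed) {
  pv <- model$presence_values; bv <- model$background_values
  if (is.null(pv) || is.null(bv))
    stop("permutation_importance: model lacks stored value tables")
  m <- nrow(pv)
  base_p <- model_scores(model, pv, clamp = FALSE)
  base_b <- model_scores(model, bv, clamp = FALSE)
  auc0 <- auc(base_p, base_b)
  vars <- model$var_names
  drops <- stats::setNames(numeric(length(vars)), vars)
  with_seed(seed, {
    for (v in vars) {
      comb <- c(pv[, v], bv[, v])
      perm <- sample(comb)
      pv2 <- pv; bv2 <- bv
      pv2[, v] <- perm[seq_len(m)]
      bv2[, v] <- perm[-seq_len(m)]
      a <- auc(model_scores(model, pv2, clamp = FALSE),
               model_scores(model, bv2, clamp = FALSE))
      drops[v] <- max(0, auc0 - a)
    }
  })
  total <- sum(drops)
  if (total <= 0) return(drops)
  100 * drops / total
}

#' Restrict a stack to a subset of layers
#'
#' @param stack A [grid_stack()].
#' @param vars Layer names to keep (order preserved as given).
#' @return A [grid_stack()] with the mask recomputed over the kept layers.
#' @export
subset_stack <- function(stack, vars) {
  missing <- setdiff(vars, names(stack$layers))
  if (length(missing))
    stop("subset_stack: no layer(s) named: ", paste(missing, collapse = ", "))
  grid_stack(stack$layers[vars])
}

#' Jackknife test of variable importance
#'
#' For every variable v, fits a model using only v and a model without v
#' (same configuration and seed as the full model) and reports the final
#' regularised training gains alongside the full-model gain. By nestedness
#' of the optimisation the full gain is never below any leave-one-out gain
#' (up to convergence tolerance).
#'
#' @param stack A [grid_stack()].
#' @param occurrences Presence points as in [maxent()].
#' @param config A [maxent_config()].
#' @return A list of class `jackknife_result`: `gain_full` and a data frame
#'   `gains` with columns `variable`, `with_only`, `without`.
#' @export
jackknife_gains <- function(stack, occurrences, config = maxent_config()) {
  vars <- names(stack$layers)
  if (length(vars) < 2) stop("jackknife_gains: need at least 2 variables")
  fit1 <- function(vs, tag) {
    tryCatch(maxent(subset_stack(stack, vs), occurrences, config),
             error = function(e)
               stop("jackknife_gains: sub-model '", tag, "' failed: ",
                    conditionMessage(e)))
  }
  full <- maxent(stack, occurrences, config)
  gains <- data.frame(variable = vars,
                      with_only = NA_real_, without = NA_real_)
  for (i in seq_along(vars)) {
    gains$with_only[i] <- fit1(vars[i], paste0("only ", vars[i]))$gain
    gains$without[i] <- fit1(setdiff(vars, vars[i]),
                             paste0("without ", vars[i]))$gain
  }
  structure(list(gain_full = full$gain, gains = gains),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("<jackknife> full-model gain %.4f\n", x$gain_full))
  print(x$gains, row.names = FALSE)
  invisible(x)
}

## ---- response curves --------------------------------------------------

#' Single-factor response curve
#'
#' Fits a maximum-entropy model on one variable alone and evaluates its
#' logistic output over evenly spaced raw-unit values spanning the
#' background range of that variable.
#'
#' @param variable Variable name (must be a stack layer).
#' @param stack A [grid_stack()].
#' @param occurrences Presence points as in [maxent()].
#' @param config A [maxent_config()].
#' @param n_points Number of evaluation points (>= 100 recommended).
#' @return A list of class `response_curve`: `variable`, `curve` (data
#'   frame `value`, `probability`), and the single-variable `model`.
#' @export
response_curve <- function(variable, stack, occurrences,
                           config = maxent_config(), n_points = 101) {
  if (!variable %in% names(stack$layers))
    stop("response_curve: no layer named '", variable, "'")
  model <- maxent(subset_stack(stack, variable), occurrences, config)
  rng <- model$scaling[[variable]]
  if (rng[2] - rng[1] <= 0)
    stop("response_curve: variable '", variable,
         "' is constant over the background (degenerate curve)")
  xs <- seq(rng[1], rng[2], length.out = max(2, n_points))
  nd <- matrix(xs, ncol = 1, dimnames = list(NULL, variable))
  p <- predict(model, nd, type = "logistic")
  structure(list(variable = variable,
                 curve = data.frame(value = xs, probability = p),
                 model = model),
            class = "response_curve")
}

#' @export
plot.response_curve <- function(x, threshold = NULL, ...) {
  graphics::plot(x$curve$value, x$curve$probability, type = "l",
                 xlab = x$variable, ylab = "existence probability",
                 ylim = c(0, 1), ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Optimal (suitable) range of a single-factor response curve
#'
#' Maximal interval(s) of the sampled range where the predicted existence
#' probability exceeds `threshold`; interval endpoints are linearly
#' interpolated between adjacent samples. An empty data frame (zero rows)
#' is a valid result when the curve never exceeds the threshold.
#'
#' @param curve A [response_curve()] result.
#' @param threshold Probability threshold (default 0.5, the conventional
#'   "suitable for growth" cut).
#' @return Data frame with columns `lower`, `upper` in raw variable units.
#' @export
optimal_range <- function(curve, threshold = 0.5) {
  x <- curve$curve$value; p <- curve$curve$probability
  above <- p > threshold
  out <- data.frame(lower = numeric(), upper = numeric())
  if (!any(above)) return(out)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  interp <- function(i1, i2) {  # crossing between samples i1 < i2
    x[i1] + (threshold - p[i1]) / (p[i2] - p[i1]) * (x[i2] - x[i1])
  }
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    lo <- if (i0 == 1) x[1] else interp(i0 - 1, i0)
    hi <- if (i1 == length(x)) x[length(x)] else interp(i1, i1 + 1)
    out[nrow(out) + 1L, ] <- c(lo, hi)
  }
  out
}
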