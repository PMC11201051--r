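## Seeded synthetic landscapes, virtual-species niches, and shifted
## scenario series: every pipeline stage gets an input with known ground
## truth.  The default extent (50 x 50 cells of 0.05 degrees starting at
## 100 E, 30 N) sits at mid-latitudes so the latitude dependence of cell
## areas is actually exercised.

#' Default header for synthetic landscapes
#'
#' @param ncols,nrows Grid dimensions (default 50 x 50).
#' @param xllcorner,yllcorner Lower-left corner, degrees (default 100 E,
#'   30 N).
#' @param cellsize Cell edge in degrees (default 0.05).
#' @return A header list usable with [env_grid()] helpers.
#' @export
synthetic_header <- function(ncols = 50, nrows = 50, xllcorner = 100,
                             yllcorner = 30, cellsize = 0.05) {
  new_grid_header(ncols, nrows, xllcorner, yllcorner, cellsize, -9999)
}

## one smooth layer: ~n_bumps random Gaussian bumps + a latitudinal
## gradient, evaluated at cell centres
smooth_field <- function(header, n_bumps = 10) {
  cells <- as.matrix(expand.grid(row = seq_len(header$nrows),
                                 col = seq_len(header$ncols)))
  cc <- cell_centres(header, cells)
  wx <- header$ncols * header$cellsize
  wy <- header$nrows * header$cellsize
  v <- numeric(nrow(cc))
  for (b in seq_len(n_bumps)) {
    cx <- header$xllcorner + stats::runif(1) * wx
    cy <- header$yllcorner + stats::runif(1) * wy
    sdv <- stats::runif(1, 0.08, 0.25) * max(wx, wy)
    amp <- stats::runif(1, -2, 2)
    v <- v + amp * exp(-((cc[, "lon"] - cx)^2 + (cc[, "lat"] - cy)^2) /
                         (2 * sdv^2))
  }
  grad <- stats::runif(1, -0.5, 0.5)
  v <- v + grad * (cc[, "lat"] - (header$yllcorner + wy / 2)) / wy * 2
  m <- matrix(NA_real_, header$nrows, header$ncols)
  m[cells] <- v
  m
}

#' Generate a stack of smooth, mutually near-independent layers
#'
#' Each layer is a sum of about ten random-centre Gaussian bumps plus a
#' latitudinal gradient, so it is spatially autocorrelated like a climate
#' surface. Each layer beyond the first is decorrelated from the already
#' accepted layers by projecting them out (a linear combination of smooth
#' fields is still a smooth field), then rescaled to its original spread;
#' the pairwise |r| bound `max_abs_r` is verified and an error raised if
#' it cannot be met (e.g. on degenerate grids).
#'
#' @param n_vars Number of layers.
#' @param header Grid header (default [synthetic_header()]).
#' @param seed Seed; the whole stack is reproducible from it.
#' @param n_bumps Gaussian bumps per layer (default 10).
#' @param max_abs_r Pairwise independence bound (default 0.3).
#' @param names Layer names (default `var1`, `var2`, ...).
#' @return A [grid_stack()].
#' @export
make_env_stack <- function(n_vars, header = synthetic_header(), seed = 1,
                           n_bumps = 10, max_abs_r = 0.3,
                           names = paste0("var", seq_len(n_vars))) {
  stopifnot(n_vars >= 1, length(names) == n_vars)
  single_cell <- header$nrows * header$ncols == 1
  with_seed(seed, {
    layers <- vector("list", n_vars)
    for (i in seq_len(n_vars)) {
      m <- smooth_field(header, n_bumps)
      if (!single_cell && i > 1) {
        # project out the accepted layers: a linear combination of smooth
        # fields is itself smooth, and the residual is exactly decorrelated
        prev <- vapply(layers[seq_len(i - 1)],
                       function(g) as.vector(g$values),
                       numeric(length(m)))
        res <- stats::lm.fit(cbind(1, prev), as.vector(m))$residuals
        if (stats::sd(res) < 1e-12)
          stop("make_env_stack: layer ", i, " degenerate after decorrelation")
        res <- res / stats::sd(res) * stats::sd(as.vector(m))
        m <- matrix(res + mean(as.vector(m)), header$nrows, header$ncols)
        for (j in seq_len(i - 1)) {
          r <- stats::cor(as.vector(m), as.vector(layers[[j]]$values))
          if (is.na(r) || abs(r) >= max_abs_r)
            stop("make_env_stack: could not decorrelate layer ", i)
        }
      }
      layers[[i]] <- env_grid(m, header$xllcorner, header$yllcorner,
                              header$cellsize, header$nodata_value,
                              name = names[i])
    }
    grid_stack(layers)
  })
}

#' Generate a layer with a target correlation to a base layer
#'
#' `new = target_r * std(base) + sqrt(1 - target_r^2) * std(noise)` with
#' white (i.i.d. normal) noise, so the achieved sample correlation is
#' within about 0.05 of the target on grids of 2500+ cells.
#'
#' @param base An [env_grid()]; must be non-constant.
#' @param target_r Target Pearson correlation in \[-1, 1\].
#' @param seed Seed for the noise field.
#' @param name Name for the new layer.
#' @return An [env_grid()] with the same header as `base`.
#' @export
make_correlated_variable <- function(base, target_r, seed = 1,
                                     name = paste0(base$name, "_cor")) {
  stopifnot(inherits(base, "env_grid"), abs(target_r) <= 1)
  v <- as.vector(base$values)
  ok <- !is.na(v)
  if (stats::sd(v[ok]) < 1e-12)
    stop("make_correlated_variable: base layer is constant")
  z <- (v - mean(v[ok])) / stats::sd(v[ok])
  noise <- with_seed(seed, stats::rnorm(length(v)))
  noise <- (noise - mean(noise[ok])) / stats::sd(noise[ok])
  newv <- target_r * z + sqrt(1 - target_r^2) * noise
  newv[!ok] <- NA
  h <- base$header
  env_grid(matrix(newv, h$nrows, h$ncols), h$xllcorner, h$yllcorner,
           h$cellsize, h$nodata_value, name = name)
}

#' Define a virtual-species niche on a stack
#'
#' True suitability is a logistic function of a quadratic form:
#' `plogis(b0 - sum_k ((x_k - optimum_k) / breadth_k)^2)`, a unimodal
#' response in each selected variable. The intercept `b0` is calibrated
#' so the mean true suitability over the stack mask equals `prevalence`.
#'
#' @param stack A [grid_stack()].
#' @param vars Names of the niche-defining variables.
#' @param optima,breadths Per-variable optimum and breadth (raw units),
#'   recycled to `length(vars)`.
#' @param prevalence Target mean suitability over the mask (default 0.25).
#' @return An object of class `synthetic_niche`: `suitability` (an
#'   `env_grid` of true suitability in (0,1)), `vars`, `optima`,
#'   `breadths`, `intercept`.
#' @export
make_niche <- function(stack, vars, optima, breadths, prevalence = 0.25) {
  stopifnot(all(vars %in% names(stack$layers)),
            prevalence > 0, prevalence < 1)
  optima <- rep_len(optima, length(vars))
  breadths <- rep_len(breadths, length(vars))
  stopifnot(all(breadths > 0))
  sv <- stack_values(stack)
  qf <- rowSums(vapply(seq_along(vars), function(k)
    ((sv$values[, vars[k]] - optima[k]) / breadths[k])^2,
    numeric(nrow(sv$values))))
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b - qf)) - prevalence,
                       lower = -60, upper = 60, tol = 1e-10)$root
  suit <- matrix(NA_real_, stack$header$nrows, stack$header$ncols)
  suit[sv$cells] <- stats::plogis(b0 - qf)
  h <- stack$header
  structure(list(
    suitability = env_grid(suit, h$xllcorner, h$yllcorner, h$cellsize,
                           h$nodata_value, name = "true_suitability"),
    vars = vars, optima = stats::setNames(optima, vars),
    breadths = stats::setNames(breadths, vars),
    intercept = b0, prevalence = prevalence), class = "synthetic_niche")
}

#' Evaluate a niche's true suitability on another stack
#'
#' Applies the niche's calibrated response to the variable values of any
#' co-registered stack (e.g. a shifted scenario), giving the ground-truth
#' suitability surface there.
#'
#' @param niche A [make_niche()] result.
#' @param stack A [grid_stack()] containing the niche variables.
#' @return An [env_grid()] of true suitability.
#' @export
niche_suitability <- function(niche, stack) {
  stopifnot(inherits(niche, "synthetic_niche"),
            all(niche$vars %in% names(stack$layers)))
  sv <- stack_values(stack)
  qf <- rowSums(vapply(seq_along(niche$vars), function(k)
    ((sv$values[, niche$vars[k]] - niche$optima[k]) / niche$breadths[k])^2,
    numeric(nrow(sv$values))))
  suit <- matrix(NA_real_, stack$header$nrows, stack$header$ncols)
  suit[sv$cells] <- stats::plogis(niche$intercept - qf)
  h <- stack$header
  env_grid(suit, h$xllcorner, h$yllcorner, h$cellsize, h$nodata_value,
           name = "true_suitability")
}

#' Sample virtual-species occurrences from a suitability surface
#'
#' Draws `n` cells with probability proportional to true suitability
#' (with replacement) and jitters each point uniformly within its cell, so
#' repeated draws of the same cell yield distinct coordinates, mirroring
#' how herbarium records scatter within a grid cell.
#'
#' @param suitability An [env_grid()] of non-negative weights.
#' @param n Number of records.
#' @param seed Seed.
#' @param species Species label.
#' @return An `occurrence_set` with `source = "synthetic"`.
#' @export
sample_occurrences <- function(suitability, n, seed = 1,
                               species = "virtual") {
  stopifnot(inherits(suitability, "env_grid"), n >= 1)
  cells <- which(!is.na(suitability$values), arr.ind = TRUE)
  w <- suitability$values[cells]
  if (any(w < 0) || sum(w) <= 0)
    stop("sample_occurrences: suitability must be non-negative with positive total")
  h <- suitability$header
  with_seed(seed, {
    pick <- sample.int(nrow(cells), n, replace = TRUE, prob = w)
    jx <- stats::runif(n); jy <- stats::runif(n)
    lon <- h$xllcorner + (cells[pick, 2] - 1 + jx) * h$cellsize
    lat <- h$yllcorner + (h$nrows - cells[pick, 1] + jy) * h$cellsize
    occurrence_set(lon, lat, species = species, source = "synthetic")
  })
}

#' Expand a base stack with redundant and noise layers
#'
#' Builds the classic variable-screening study condition: the base layers
#' plus `n_redundant` correlated copies of them (targets drawn uniformly
#' from `target_r`, assigned round-robin over the bases, built with
#' [make_correlated_variable()]) plus `n_noise` white-noise layers with no
#' spatial structure or association. Copy layers are named
#' `<base>_r<k>`, noise layers `noise<k>`.
#'
#' @param base A [grid_stack()] of informative layers.
#' @param n_redundant Number of correlated copies to add.
#' @param target_r Range (length 2) of target correlations for the copies
#'   (default `c(0.85, 0.95)`, comfortably above the usual 0.8 screening
#'   cut).
#' @param n_noise Number of pure-noise layers to add.
#' @param seed Seed.
#' @return A [grid_stack()] with `length(base$layers) + n_redundant +
#'   n_noise` layers (bases first, in their original order).
#' @export
make_redundant_stack <- function(base, n_redundant, target_r = c(0.85, 0.95),
                                 n_noise = 0, seed = 1) {
  stopifnot(inherits(base, "grid_stack"), n_redundant >= 0, n_noise >= 0)
  nb <- length(base$layers)
  h <- base$header
  layers <- base$layers
  with_seed(seed, {
    copy_count <- integer(nb)
    for (i in seq_len(n_redundant)) {
      bi <- (i - 1L) %% nb + 1L
      copy_count[bi] <- copy_count[bi] + 1L
      r <- stats::runif(1, target_r[1], target_r[2])
      nm <- paste0(names(base$layers)[bi], "_r", copy_count[bi])
      layers[[nm]] <- make_correlated_variable(
        base$layers[[bi]], r, seed = sample.int(2^30, 1), name = nm)
    }
    for (k in seq_len(n_noise)) {
      nm <- paste0("noise", k)
      m <- matrix(stats::rnorm(h$nrows * h$ncols), h$nrows, h$ncols)
      m[is.na(base$layers[[1]]$values)] <- NA
      layers[[nm]] <- env_grid(m, h$xllcorner, h$yllcorner, h$cellsize,
                               h$nodata_value, name = nm)
    }
  })
  grid_stack(layers)
}

#' Build a series of shifted climate scenarios
#'
#' Produces one stack per scenario by adding constant offsets to chosen
#' variables (exact addition; all other layers are shared). With a niche
#' held fixed, a positive shift on a niche variable moves the suitable
#' region toward where the unshifted variable was lower, giving a known
#' expected direction of centroid migration.
#'
#' @param stack The baseline ("current") [grid_stack()].
#' @param shifts Named list: scenario name -> named numeric vector of
#'   per-variable additive offsets.
#' @param baseline_name Name for the unshifted entry (default
#'   `"current"`).
#' @return An object of class `scenario_series`: named list of stacks
#'   (baseline first) plus the recorded `shifts`.
#' @export
make_scenario_series <- function(stack, shifts, baseline_name = "current") {
  stopifnot(inherits(stack, "grid_stack"), is.list(shifts))
  out <- stats::setNames(list(stack), baseline_name)
  for (sc in names(shifts)) {
    sh <- shifts[[sc]]
    missing <- setdiff(names(sh), names(stack$layers))
    if (length(missing))
      stop("make_scenario_series: shift variable(s) not in stack: ",
           paste(missing, collapse = ", "))
    layers <- stack$layers
    for (v in names(sh)) {
      g <- layers[[v]]
      g$values <- g$values + sh[[v]]
      layers[[v]] <- g
    }
    out[[sc]] <- grid_stack(layers)
  }
  structure(list(stacks = out, shifts = shifts,
                 baseline = baseline_name), class = "scenario_series")
}

#' @export
print.scenario_series <- function(x, ...) {
  cat(sprintf("<scenario_series> baseline '%s' + %d scenario(s): %s\n",
              x$baseline, length(x$stacks) - 1,
              paste(setdiff(names(x$stacks), x$baseline), collapse = ", ")))
  invisible(x)
}
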