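# Independent oracles and small fixture builders shared across test files.

# brute-force pairwise AUC: mean over all (presence, background) pairs of
# 1 / 0.5 / 0 for win / tie / loss
auc_brute <- function(p, b) {
  s <- 0
  for (x in p) for (y in b) s <- s + if (x > y) 1 else if (x == y) 0.5 else 0
  s / (length(p) * length(b))
}

# great-circle oracle on the package's sphere, via geosphere
dist_oracle_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(c(lon1, lat1), c(lon2, lat2), r = 6371008.8) / 1000
}

# tiny env_grid with sequential values
tiny_grid <- function(nrows = 3, ncols = 3, xll = 0, yll = 0, cs = 1,
                      name = "g", values = NULL) {
  if (is.null(values))
    values <- matrix(seq_len(nrows * ncols), nrows, ncols)
  env_grid(values, xll, yll, cs, -9999, name = name)
}

# regularised maxent objective, written independently of the fitter
maxent_objective <- function(lambda, P, B, beta) {
  mean(P %*% lambda) - log(mean(exp(B %*% lambda))) - sum(beta * abs(lambda))
}

# a small fitted world reused by several test files
small_world <- function(seed = 11, n_vars = 3, n_occ = 250,
                        prevalence = 0.08, breadth_frac = 0.3) {
  st <- make_env_stack(n_vars, seed = seed)
  v1 <- as.vector(st$layers$var1$values)
  ni <- make_niche(st, "var1",
                   optima = unname(stats::quantile(v1, 0.55)),
                   breadths = breadth_frac * stats::sd(v1),
                   prevalence = prevalence)
  occ <- sample_occurrences(ni$suitability, n_occ, seed = seed + 1)
  list(stack = st, niche = ni, occ = occ)
}

# quick-converging config for small fits
quick_config <- function(seed = 1, ...) {
  maxent_config(seed = seed, hinge_knots = 5, max_iterations = 400,
                tolerance = 1e-4, ...)
}
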