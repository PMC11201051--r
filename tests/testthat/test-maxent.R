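# The 4-cell binary-feature toy has a closed form: with background feature
# values (1,1,0,0) and presence mean 0.75, the unpenalised optimum solves
# e^l / (e^l + 1) = 0.75, i.e. l = ln 3, and the raw distribution is
# (0.375, 0.375, 0.125, 0.125).
toy_B <- matrix(c(1, 1, 0, 0), ncol = 1, dimnames = list(NULL, "f"))
toy_P <- matrix(c(1, 1, 1, 0), ncol = 1, dimnames = list(NULL, "f"))
toy_cfg <- maxent_config(reg_multiplier = 0, tolerance = 1e-10,
                         max_iterations = 500)

test_that("the binary toy recovers lambda = ln 3 and its raw distribution", {
  m <- fit_maxent(toy_P, toy_B, toy_cfg)
  expect_equal(unname(m$lambdas), log(3), tolerance = 1e-6)
  expect_equal(predict(m, type = "raw"), c(0.375, 0.375, 0.125, 0.125),
               tolerance = 1e-8)
  expect_equal(sum(predict(m, type = "raw")), 1, tolerance = 1e-9)
})

test_that("an L1 penalty leaves the KKT gap exactly at beta", {
  beta <- 0.05
  m <- fit_maxent(toy_P, toy_B, toy_cfg, beta = beta)
  q <- predict(m, type = "raw")
  gap <- abs(sum(q * toy_B[, 1]) - mean(toy_P[, 1]))
  expect_equal(gap, beta, tolerance = 1e-6)
  # independent 1-parameter oracle
  l_star <- optimize(function(l) maxent_objective(l, toy_P, toy_B, beta),
                     c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(unname(m$lambdas), l_star, tolerance = 1e-5)
})

test_that("a uniform environment yields the null model", {
  B <- matrix(1, 8, 2, dimnames = list(NULL, c("a", "b")))
  P <- matrix(1, 4, 2, dimnames = list(NULL, c("a", "b")))
  m <- fit_maxent(P, B, toy_cfg)
  expect_equal(unname(m$lambdas), c(0, 0))
  expect_equal(m$gain, 0)
  expect_equal(predict(m, type = "raw"), rep(1 / 8, 8))
  # null model: e^H * q = 1, logistic exactly 0.5 everywhere
  expect_equal(predict(m, type = "logistic"), rep(0.5, 8))
})

test_that("logistic output matches the hand formula and is monotone in q", {
  m <- fit_maxent(toy_P, toy_B, toy_cfg)
  q <- predict(m, type = "raw")
  H <- -sum(q * log(q))
  expect_equal(m$entropy, H, tolerance = 1e-9)
  expect_equal(predict(m, type = "logistic"),
               exp(H) * q / (1 + exp(H) * q), tolerance = 1e-9)
  # doubling q strictly increases the logistic value
  p1 <- exp(H) * 0.1 / (1 + exp(H) * 0.1)
  p2 <- exp(H) * 0.2 / (1 + exp(H) * 0.2)
  expect_gt(p2, p1)
})

test_that("KKT box condition holds against a generic optimiser on random instances", {
  set.seed(77)
  for (inst in 1:20) {
    K <- sample(2:3, 1); n <- sample(8:14, 1); m <- sample(4:7, 1)
    B <- matrix(rnorm(n * K), n, K, dimnames = list(NULL, letters[1:K]))
    # presences are background rows, so presence means lie inside the
    # convex hull of background features and the optimum is finite
    P <- B[sample(n, m, replace = TRUE), , drop = FALSE]
    beta <- runif(K, 0.01, 0.08)
    fit <- fit_maxent(P, B, maxent_config(tolerance = 1e-9,
                                          max_iterations = 3000),
                      beta = beta)
    # KKT: |E_q f - mean_pres f| <= beta (+ slack), tight for active lambdas
    q <- predict(fit, type = "raw")
    for (j in 1:K) {
      gap <- abs(sum(q * B[, j]) - mean(P[, j]))
      expect_lte(gap, beta[j] + 1e-4)
      if (abs(fit$lambdas[j]) > 1e-6)
        expect_lt(abs(gap - beta[j]), 1e-4)  # active features sit on the box
    }
    # objective value matches a Nelder-Mead oracle
    or <- optim(rep(0, K), function(l) -maxent_objective(l, P, B, beta),
                method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 20000))
    expect_equal(maxent_objective(fit$lambdas, P, B, beta), -or$value,
                 tolerance = 1e-4)
  }
})

test_that("the gain trace is non-decreasing and the raw distribution normalised", {
  w <- small_world(seed = 31, n_occ = 120)
  m <- maxent(w$stack, w$occ, quick_config(seed = 2))
  expect_true(all(diff(m$gain_trace$gain) >= -1e-12))
  expect_true(all(m$gain_trace$delta >= 0))
  expect_equal(sum(predict(m, type = "raw")), 1, tolerance = 1e-9)
  expect_true(m$entropy >= 0 && m$entropy <= log(m$n_background) + 1e-9)
})

test_that("feature construction matches its contracts", {
  w <- small_world(seed = 5, n_occ = 60)
  cfg <- maxent_config(seed = 4, hinge_knots = 10)
  feats <- build_features(w$stack, w$occ, cfg)
  defs <- feats$defs

  # linear feature equals the scaled value
  sv <- feats$background_values[, "var1"]
  rng <- feats$scaling[["var1"]]
  lin <- feats$background[, "lin(var1)"]
  expect_equal(lin, (sv - rng[1]) / (rng[2] - rng[1]), ignore_attr = TRUE)

  # product feature is the elementwise product of scaled values
  l1 <- feats$background[, "lin(var1)"]; l2 <- feats$background[, "lin(var2)"]
  expect_equal(feats$background[, "prod(var1,var2)"], l1 * l2,
               ignore_attr = TRUE)

  # hinge knots sit at equally spaced interior quantiles of the background
  kn <- sort(defs$knot[defs$kind == "forward_hinge" & defs$var == "var1"])
  want <- unname(quantile(lin, probs = (1:10) / 11, type = 7))
  expect_equal(kn, want[seq_along(kn)], tolerance = 1e-9)

  # background sampling is deterministic given the seed
  feats2 <- build_features(w$stack, w$occ, cfg)
  expect_identical(feats$bg_cells, feats2$bg_cells)
})

test_that("a constant variable keeps only its linear feature", {
  st <- make_env_stack(2, seed = 8)
  flat <- st$layers$var2
  flat$values[] <- 3.3
  st2 <- grid_stack(list(st$layers$var1, flat))
  occ <- small_world(seed = 8, n_occ = 50)$occ
  feats <- build_features(st2, occ, quick_config(seed = 1))
  kinds <- feats$defs$kind[feats$defs$var == "var2"]
  expect_identical(unique(kinds), "linear")
})

test_that("percent contribution normalises to 100 and ranks signal over noise", {
  w <- small_world(seed = 13, n_occ = 250)
  m <- maxent(w$stack, w$occ, quick_config(seed = 6))
  pc <- percent_contribution(m)
  expect_equal(sum(pc), 100, tolerance = 0.2)
  expect_true(all(pc >= 0))
  expect_gt(pc[["var1"]], max(pc[c("var2", "var3")]))

  # single-variable model: 100% to that variable
  m1 <- maxent(subset_stack(w$stack, "var1"), w$occ, quick_config(seed = 6))
  expect_equal(unname(percent_contribution(m1)), 100, tolerance = 0.2)
})

test_that("duplicated variables still share 100% deterministically", {
  st <- make_env_stack(1, seed = 17)
  dup <- st$layers$var1
  dup$name <- "var1b"
  st2 <- grid_stack(list(st$layers$var1, dup))
  w <- small_world(seed = 17, n_occ = 120, n_vars = 1)
  m <- maxent(st2, w$occ, quick_config(seed = 2))
  pc <- percent_contribution(m)
  expect_equal(sum(pc), 100, tolerance = 0.2)
  m2 <- maxent(st2, w$occ, quick_config(seed = 2))
  expect_equal(percent_contribution(m2), pc)
})

test_that("permutation importance is deterministic, normalised, and ranks signal", {
  w <- small_world(seed = 13, n_occ = 250)
  m <- maxent(w$stack, w$occ, quick_config(seed = 6))
  pi1 <- permutation_importance(m, seed = 99)
  pi2 <- permutation_importance(m, seed = 99)
  expect_equal(pi1, pi2)
  expect_equal(sum(pi1), 100, tolerance = 0.2)
  expect_true(all(pi1 >= 0))
  expect_gt(pi1[["var1"]], max(pi1[c("var2", "var3")]))

  m1 <- maxent(subset_stack(w$stack, "var1"), w$occ, quick_config(seed = 6))
  expect_equal(unname(permutation_importance(m1, seed = 1)), 100)
})

test_that("permuting a constant variable has zero importance", {
  st <- make_env_stack(2, seed = 19)
  flat <- st$layers$var2
  flat$values[] <- 1
  st2 <- grid_stack(list(st$layers$var1, flat))
  w <- small_world(seed = 19, n_occ = 100)
  m <- maxent(st2, w$occ, quick_config(seed = 3))
  pi <- permutation_importance(m, seed = 4)
  expect_equal(pi[["var2"]], 0)
})

test_that("jackknife gains obey nestedness and vanish for a constant variable", {
  st <- make_env_stack(3, seed = 23)
  flat <- st$layers$var3
  flat$values[] <- 7
  st2 <- grid_stack(list(st$layers$var1, st$layers$var2, flat))
  w <- small_world(seed = 23, n_occ = 150)
  jk <- jackknife_gains(st2, w$occ, quick_config(seed = 5))
  expect_true(all(jk$gains$with_only >= -1e-9))
  expect_true(all(jk$gains$without >= -1e-9))
  expect_equal(jk$gains$with_only[jk$gains$variable == "var3"], 0,
               tolerance = 1e-9)
  # full-model gain dominates every leave-one-out gain (nested optimisation)
  expect_true(all(jk$gain_full >= jk$gains$without - 1e-3))
})

test_that("jackknife isolates the true variable of a one-variable niche", {
  w <- small_world(seed = 29, n_occ = 250)
  jk <- jackknife_gains(w$stack, w$occ, quick_config(seed = 7))
  g1 <- jk$gains$with_only[jk$gains$variable == "var1"]
  expect_gt(g1, max(jk$gains$with_only[jk$gains$variable != "var1"]))
  expect_equal(g1, jk$gain_full, tolerance = 0.1 * jk$gain_full)
})

test_that("projection clamps to the training range and is the identity on it", {
  w <- small_world(seed = 37, n_occ = 150)
  m <- maxent(w$stack, w$occ, quick_config(seed = 8))
  tr <- predict(m, w$stack)
  tr2 <- project_suitability(m, w$stack)
  expect_equal(tr2$values, tr$values)

  # push var1 far above its training max: clamped projection equals the
  # projection of a stack clamped by hand
  ser <- make_scenario_series(w$stack, list(hot = c(var1 = 1e6)))
  hot <- project_suitability(m, ser$stacks$hot)
  clamped <- w$stack
  clamped$layers$var1$values[] <- m$scaling[["var1"]][2]
  expect_equal(hot$values, project_suitability(m, clamped)$values,
               tolerance = 1e-12)

  # nodata cells propagate
  g <- w$stack$layers$var1
  g$values[1, 1] <- NA
  st2 <- grid_stack(list(g, w$stack$layers$var2, w$stack$layers$var3))
  pr <- project_suitability(m, st2)
  expect_true(is.na(pr$values[1, 1]))
})

test_that("projection onto a shifted scenario moves suitability with the shift", {
  # one-variable niche: shifting the variable up relocates high suitability
  # to cells whose original value sat below the optimum by the shift
  w <- small_world(seed = 41, n_occ = 250)
  m <- maxent(subset_stack(w$stack, "var1"), w$occ, quick_config(seed = 9))
  delta <- 0.8 * sd(as.vector(w$stack$layers$var1$values))
  ser <- make_scenario_series(w$stack, list(up = c(var1 = delta)))
  cur <- predict(m, subset_stack(ser$stacks$current, "var1"))
  fut <- predict(m, subset_stack(ser$stacks$up, "var1"))
  v <- w$stack$layers$var1$values
  opt_band <- function(x, centre, width) !is.na(x) & abs(x - centre) < width
  centre_fut <- w$niche$optima[["var1"]] - delta
  width <- w$niche$breadths[["var1"]]
  # cells now sitting at the optimum under the shift gain suitability
  gain_cells <- opt_band(v, centre_fut, width) & !opt_band(v, w$niche$optima[["var1"]], width)
  expect_gt(sum(gain_cells, na.rm = TRUE), 10)
  expect_gt(mean(fut$values[gain_cells] - cur$values[gain_cells]), 0)
})

test_that("missing variables raise schema errors", {
  w <- small_world(seed = 43, n_occ = 80)
  m <- maxent(w$stack, w$occ, quick_config(seed = 1))
  expect_error(predict(m, subset_stack(w$stack, c("var1", "var2"))),
               "var3")
})

test_that("single-factor response curves are bounded, shaped, and peak near truth", {
  w <- small_world(seed = 47, n_occ = 300, breadth_frac = 0.25)
  rc <- response_curve("var1", w$stack, w$occ, quick_config(seed = 10))
  expect_true(all(rc$curve$probability >= 0 & rc$curve$probability <= 1))
  expect_gte(nrow(rc$curve), 100)
  # peak within 10% of the sampled range of the true optimum
  peak <- rc$curve$value[which.max(rc$curve$probability)]
  rng <- diff(range(rc$curve$value))
  expect_lt(abs(peak - w$niche$optima[["var1"]]), 0.1 * rng)

  # a linear-only model yields a monotone curve
  rc_lin <- response_curve("var1", w$stack, w$occ,
                           maxent_config(seed = 10,
                                         feature_classes = "linear"))
  d <- diff(rc_lin$curve$probability)
  expect_true(all(d >= -1e-12) || all(d <= 1e-12))
})

test_that("a constant variable yields a degenerate-curve error", {
  st <- make_env_stack(2, seed = 53)
  flat <- st$layers$var2
  flat$values[] <- 0
  st2 <- grid_stack(list(st$layers$var1, flat))
  occ <- small_world(seed = 53, n_occ = 60)$occ
  expect_error(response_curve("var2", st2, occ, quick_config(seed = 1)),
               "constant")
})

test_that("optimal ranges interpolate threshold crossings", {
  # p(x) = x on [0, 1]: range (0.5, 1]
  fake <- structure(list(variable = "x",
                         curve = data.frame(value = seq(0, 1, 0.01),
                                            probability = seq(0, 1, 0.01))),
                    class = "response_curve")
  r <- optimal_range(fake, 0.5)
  expect_equal(nrow(r), 1)
  expect_equal(r$lower, 0.5, tolerance = 1e-9)
  expect_equal(r$upper, 1)

  # flat curve below threshold: empty result, not an error
  flat <- structure(list(variable = "x",
                         curve = data.frame(value = seq(0, 1, 0.01),
                                            probability = rep(0.4, 101))),
                    class = "response_curve")
  expect_equal(nrow(optimal_range(flat, 0.5)), 0)
})

test_that("optimal range matches a dense-grid brute-force scan", {
  f <- function(x) 0.9 * exp(-(x - 0.4)^2 / 0.02)
  xs <- seq(0, 1, length.out = 101)
  samp <- structure(list(variable = "x",
                         curve = data.frame(value = xs,
                                            probability = f(xs))),
                    class = "response_curve")
  r <- optimal_range(samp, 0.5)
  dense <- seq(0, 1, length.out = 100001)
  above <- dense[f(dense) > 0.5]
  step <- diff(xs)[1]
  expect_equal(nrow(r), 1)
  expect_lt(abs(r$lower - min(above)), step)
  expect_lt(abs(r$upper - max(above)), step)
})
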