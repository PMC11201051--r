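---
title: "Methods: maximum-entropy niche modelling and range-change analysis with maxniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum-entropy niche modelling and range-change analysis with maxniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

maxniche implements a complete species-distribution-modelling workflow of
the kind used to map habitat suitability for a plant species across past,
present and future climate: occurrence thinning, environmental-variable
screening, a maximum-entropy suitability model, replicate evaluation by
AUC, habitat classification with spherical area accounting, binary
range-change algebra, and centroid-migration geometry. This vignette
documents the model, its assumptions, the numerical choices, and what the
synthetic-data tests do and do not demonstrate.

## The model

Let $x$ index the cells of a study region (the *background*) and let
$f_1(x), \dots, f_K(x)$ be features derived from environmental variables.
The model is the Gibbs distribution over background cells

$$ q_\lambda(x) \;=\; \frac{\exp\!\big(\sum_j \lambda_j f_j(x)\big)}{Z(\lambda)},
\qquad Z(\lambda) = \sum_{x \in \mathrm{bg}} \exp\!\big(\textstyle\sum_j \lambda_j f_j(x)\big), $$

the maximum-entropy distribution subject to moment constraints on the
presence sample. Fitting maximises the **regularised training gain**

$$ G(\lambda) \;=\; \frac{1}{m}\sum_{i=1}^{m} \log q_\lambda(x_i)
   \;+\; \log n_{\mathrm{bg}} \;-\; \sum_j \beta_j |\lambda_j|, $$

the mean presence log-density relative to the uniform baseline (so
$G(0)=0$), minus an L1 penalty. At the optimum the Karush–Kuhn–Tucker
conditions give the *box constraint*
$|\mathbb{E}_q[f_j] - \bar f_j^{\mathrm{pres}}| \le \beta_j$, with
equality for features with non-zero weight; the test suite verifies this
against an independent generic optimiser on small random instances, and
against the closed form $\lambda = \ln 3$ on a four-cell binary-feature
toy.

**Features.** Variables are scaled per variable to $[0,1]$ by the
background minimum and maximum. The expansion comprises linear,
quadratic, pairwise-product, forward-hinge and reverse-hinge features by
default (threshold features are available but off: hinges span the same
expressiveness class with smoother fits and smaller models). Hinge and
threshold knots sit at equally spaced *interior* quantiles
$k/(K{+}1),\,k=1..K$ of the scaled background values — not at the decile
boundaries including 0 and 1, which would duplicate the linear feature
(forward hinge at 0) or be degenerate (reverse hinge at 0). Nonlinear
features of a variable that is constant on the background are omitted.

**Regularisation.** $\beta_j = r \cdot \beta_{\mathrm{class}(j)} \cdot
\mathrm{sd}_{\mathrm{bg}}(f_j) / \sqrt{m}$ with class constants 0.05
(linear, quadratic, product), 0.5 (hinge), 1.0 (threshold) and global
multiplier $r$ (default 1). These are fixed, documented constants: the
goal is a reproducible, self-contained formulation, not bit-compatibility
with any external software.

**Optimiser.** Cyclic coordinate descent in a fixed cycle (feature
construction order). Each coordinate takes a damped Newton step with L1
soft-thresholding, accepted only if the exact objective does not
decrease (step halving otherwise), so the gain trace is non-decreasing by
construction. A damped Newton step reaches the same fixed point as an
exact per-coordinate line search — the KKT box is what the tests assert —
at a fraction of the per-cycle cost. Convergence is declared when a full
cycle improves the gain by less than `tolerance` (relative, default
1e-5); the per-feature KKT residual at that point is small but can exceed
`tolerance` itself, which is why correctness tests that need tight
optima pass a tighter tolerance.

**Outputs.** The *raw* output is $q_\lambda$ (sums to 1 over the training
background). The *logistic* output is
$p = e^H q / (1 + e^H q)$ with $H$ the entropy of the fitted raw
distribution, the standard post-transform under a default prevalence
assumption of 0.5: a "typical" presence scores about 0.5, and the null
(uniform) model scores exactly 0.5 everywhere. Projection onto another
raster stack **clamps** variable values to the training range by default,
the usual guard against extrapolating feature responses.

**Variable importance.** *Percent contribution* credits each accepted
coordinate step's gain increase to the stepped feature's variable
(product features split 50/50); because the cycle order is fixed, the
crediting is deterministic. With strongly collinear variables the split
within a correlated group is order-dependent — an intrinsic property of
path-based crediting, which is why contribution is read alongside
*permutation importance* (drop in training AUC when one variable's values
are permuted jointly across presences and background, floored at 0,
rescaled to 100) and the *jackknife* gains (refit with only / without
each variable).

## Screening

Two stages, mirroring standard practice:

1. **Zero-contribution elimination.** Fit on the current set, drop every
   variable whose percent contribution is below `epsilon_zero` (default
   1e-6 percentage points, i.e. "printed zero"), repeat until stable.
2. **Correlation filter.** Pearson correlations are computed at the
   *presence points* (the default, matching how such tables are usually
   produced by extracting values at distribution points; background-based
   correlation can be had by passing those values instead). Pairs are
   processed in decreasing $|r|$; in each pair above the threshold
   (default 0.8) whose members both survive, the lower-contribution
   member is dropped, ties dropping the later variable in input order.
   The processing order and tie-break are fixed purely for determinism.

A consequence of presence-point correlation worth knowing: at the
presence points of a narrow-niche species the niche variable has
restricted range, which *attenuates* its correlation with near-duplicate
variables. Only very tightly correlated duplicates (sample $|r| \gtrsim
0.98$ on the full grid) reliably exceed a 0.8 cut at presence points —
the situation of the bioclim temperature family, and the regime the
synthetic screening condition emulates.

## Evaluation

Replicate train/test splits hold out `floor(test_fraction * n)` presences
(default 25%), deterministically from (seed, replicate index). Test
presences are scored against the background sample (presence-background
AUC, computed by midranks; equal to the brute-force pair statistic, ties
counting one half). Grades follow the conventional half-open bands
(0.9–1.0 "excellent", 0.8–0.9 "good", 0.7–0.8 "average", 0.6–0.7 "poor",
0.1–0.6 "failure"). The suitability map carried downstream is the
cell-wise mean of the replicate logistic maps; whether published maps are
replicate means or single runs is often unstated, and the mean is fixed
here because it is reproducible and matches the "average" reporting of
common tooling.

## Habitat classification, areas, change, centroids

Suitability is classified as unsuitable $[0, 0.1)$, low $[0.1, 0.3)$,
medium $[0.3, 0.5)$ and high $[0.5, 1]$. The binary presence–absence
matrix uses the strict rule $p > 0.5$. The two conventions disagree on a
cell at exactly 0.5 (high class, but absent from the binary range); both
are kept deliberately because that is how the fixed-threshold
classification and the ">0.50" presence rule are stated in the
literature this workflow follows, and the discrepancy is pinned by a
test.

Cell areas use the spherical quadrangle formula
$A = R^2 \,\Delta\lambda\, (\sin\varphi_{\mathrm{top}} -
\sin\varphi_{\mathrm{bottom}})$ on the authalic sphere
$R = 6371.0088$ km — the single geodesy constant shared with the
haversine distance and thinning. Areas are reported in $10^4$ km$^2$
with signed deltas against a named baseline, at full precision
internally and 2 decimals in output files; because each printed column is
rounded independently, printed identities (total = low+medium+high,
net = expansion − contraction) can be off by one unit in the last digit
even though they hold exactly internally.

Range change between two binary maps is per-cell algebra:
(0,0) absent, (0,1) expansion, (1,1) retention, (1,0) contraction, with
the exact identities retention + contraction = current area and
retention + expansion = future area. The range **centroid** is the
area-weighted mean of presence-cell centres (weights = spherical cell
areas; unweighted available via `area_weighted = FALSE`) — area weighting
is the geometrically correct reading of "geometric centre" on a lat/lon
grid, where cells shrink poleward. Migration vectors report the
haversine distance and initial bearing.

Nodata handling, which published area tables rarely state: all area
accounting runs over the stack mask (cells valid in every layer), so
ocean/nodata cells contribute to no class and the per-class areas always
sum to the masked grid area.

## The synthetic-data generator

The generator provides seeded ground truth for every stage:

* `make_env_stack()` — smooth layers (sums of ~10 Gaussian bumps plus a
  latitudinal gradient) on a default 50×50 grid of 0.05° cells at
  lon 100–102.5°E, lat 30–32.5°N; mid-latitude on purpose, so
  area-weighting is exercised. Layers are mutually decorrelated
  (pairwise $|r| < 0.3$) by projecting out accepted layers.
* `make_correlated_variable()` — a copy with a target correlation,
  using a *white-noise* residual so the achieved $|r|$ lands within
  ±0.05 of the target on 2500-cell grids (a spatially smooth residual
  would leave far larger sampling error at the grid's effective sample
  size).
* `make_niche()` — true suitability `plogis(b0 − Σ((x−opt)/breadth)²)`,
  unimodal in each niche variable, with the intercept calibrated by
  root-finding so mean suitability equals a target prevalence.
* `sample_occurrences()` — cells drawn with probability proportional to
  true suitability, with replacement, jittered uniformly within the
  cell.
* `make_redundant_stack()` / `make_scenario_series()` — near-duplicate
  and noise layers for screening studies; exact additive shifts for
  future-scenario studies, whose effect on the *true* range centroid is
  computable directly.

**Frozen study conditions.** The end-to-end recovery study uses: 8
informative base layers + 26 near-duplicates ($r \in [0.985, 0.995]$) +
2 noise layers (36 candidates, the size of a typical bioclim + solar +
soil candidate set); a sharp two-variable niche (breadth 0.22 bg-sd per
variable) at prevalence 0.05 — chosen because the high-suitability share
of a real medicinal-plant study region is of the order of a few percent;
500 sampled records thinned at 5 km (~130–180 survivors on ~5.5 km
cells); screening with linear/quadratic/hinge features (5 knots), and
20 evaluation replicates rather than 100 to keep the study tractable at
desk scale while leaving the mean AUC stable to well under the margins
being asserted. These values were fixed at design time from the
considerations above and are not tuned per run.

**What passing these tests shows — and does not.** On these landscapes
the pipeline retains the true niche variables, collapses the redundant
family, discriminates presences with mean test AUC > 0.9, brackets the
true single-factor optimum, and moves the predicted range centroid in
the direction computed from the true suitability surface under an exact
scenario shift (the direction check is a frozen-seed property: with an
unlucky landscape realisation the model's binary range can under-shift).
Real occurrence data differ in ways the generator deliberately does not
emulate: sampling bias toward roads and herbaria, positional error,
non-equilibrium distributions, and the covariance structure of real
climate fields. Passing here validates the *machinery*, not any claim
about a particular species.

## Numerical choices and degenerate inputs

* Header comparison tolerance 1e-9°; ESRI ASCII values serialised with
  12 significant digits so probabilities survive a round-trip within
  1e-9. Both `xllcorner` and `xllcenter` dialects are read; `xllcorner`
  is always written.
* Cell membership is half-open: the lower/left edge belongs to the cell,
  the upper/right edge to the next. Points outside the grid or on masked
  cells are returned in a rejection table, never silently dropped.
* Thinning is greedy first-come in input order (kept iff ≥ radius from
  every already-kept point, strictly-closer points discarded):
  deterministic, idempotent, order-stable. Optimal (retention-maximising)
  thinning is deliberately out of scope.
* Constant variables: linear feature kept (weight irrelevant), nonlinear
  features omitted; zero variance at presence points drops a variable
  from the correlation filter as "degenerate"; a constant single-factor
  curve is an error.
* A fit that exhausts `max_iterations` carries a warning and
  `converged = FALSE` rather than raising.
* Empty binary ranges make `range_centroid()` error (there is no
  centroid); an optimal range that never crosses the threshold is an
  empty data frame (a valid result).
* The pipeline derives stage seeds from the master seed by a fixed
  counter scheme, so stages are independently reproducible and a re-run
  with the same configuration is artifact-identical (timing log aside).

## Known limitations

* Percent contributions within a group of highly collinear variables are
  path-dependent (shared credit); rely on permutation importance and
  jackknife for those.
* The logistic output inherits the usual caveat that it is a calibrated
  index, not an occupancy probability.
* No categorical features, sample-bias grids, cloglog output, or
  spatial-block cross-validation; no reprojection or resampling (stacks
  must be co-registered on input).
* Presence-point correlation screening attenuates under narrow niches
  (see above); the option of supplying background values to
  `correlation_filter()` exists for exactly that case.
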