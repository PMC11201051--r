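# maxniche

Maximum-entropy niche modelling and habitat range-change analysis in R.

Species distribution modellers routinely answer a chain of questions for
a focal species — often a wild-harvested medicinal plant whose cultivation
must be sited: *which environmental factors govern its distribution, where
is habitat suitable today, how much area is suitable per class, and where
does the suitable range (and its centroid) move under past and future
climates?* maxniche implements that entire chain as a tested, reusable R
package: no external GIS or modelling software is involved, and every step
is reproducible from a seed.

## What's inside

The core is a from-scratch **maximum-entropy (Gibbs) suitability model**
over background cells. With features $f_j(x)$ built from environmental
layers (linear, quadratic, product, hinge), the model is

$$ q_\lambda(x) = \frac{e^{\sum_j \lambda_j f_j(x)}}{Z(\lambda)}, $$

fitted by maximising the L1-regularised training gain
$\tfrac1m\sum_i \log q_\lambda(x_i) + \log n_{bg} - \sum_j \beta_j|\lambda_j|$
with cyclic coordinate descent; the logistic output
$p = e^H q/(1+e^H q)$ (H = entropy of the fitted distribution) is the
habitat-suitability index in (0, 1). Around it:

* `read_asc()` / `write_asc()` / `grid_stack()` / `extract_values()` —
  ESRI ASCII grid I/O and co-registered raster stacks with explicit
  nodata masks and rejection reporting.
* `read_occurrences()` / `thin_occurrences()` — occurrence ingestion and
  deterministic 5-km spatial thinning (greedy, great-circle).
* `screen_variables()` — two-stage variable screening: iterative
  zero-contribution elimination, then pairwise Pearson filtering at
  presence points (|r| > 0.8 drops the lower-contribution member).
* `maxent()` — the fitting function (returns a classed model with
  `print`, `summary`, `coef`, `predict`, `plot` methods), plus
  `percent_contribution()`, `permutation_importance()`,
  `jackknife_gains()`, `response_curve()`, `optimal_range()`.
* `evaluate_replicates()` — 75/25 train/test replicates scored by
  presence-background AUC with the conventional grade bands, and the
  replicate-mean suitability map.
* `classify_suitability()` / `class_areas()` / `binary_map()` /
  `change_map()` / `range_centroid()` / `migration_vector()` — the
  four-class habitat map (0.1 / 0.3 / 0.5 thresholds), areas in
  10^4 km^2 on the authalic sphere with signed deltas,
  expansion/retention/contraction algebra, and centroid migration by
  haversine distance and bearing.
* `make_env_stack()` and friends — a seeded synthetic-landscape and
  virtual-species generator, so the whole pipeline is testable against
  known ground truth.
* `run_full_pipeline()` — one-call orchestration with a fixed artifact
  layout and a JSON provenance record.

See `vignettes/maxniche-methods.Rmd` for the full model description,
parameter defaults, and design rationale.

## Worked example

A virtual species on a synthetic landscape, end to end:

```r
library(maxniche)

stack <- make_env_stack(4, seed = 42)                   # 50x50, 0.05 deg cells
v1    <- as.vector(stack$layers$var1$values)
niche <- make_niche(stack, "var1", optima = quantile(v1, 0.55),
                    breadths = 0.25 * sd(v1), prevalence = 0.06)
occ   <- thin_occurrences(sample_occurrences(niche$suitability, 400, seed = 43), 5)
nrow(occ)
#> [1] 225

cfg <- maxent_config(seed = 44, hinge_knots = 6, max_iterations = 500,
                     tolerance = 1e-4)
ev  <- evaluate_replicates(stack, occ, cfg, replicates = 10, seed = 45)
ev
#> <maxent_eval> 10 replicate(s); mean test AUC 0.838 (good), range [0.799, 0.848]

model <- maxent(stack, occ, cfg)
round(percent_contribution(model), 2)
#>  var1  var2  var3  var4
#> 96.76  1.44  1.28  0.52

class_areas(classify_suitability(ev$mean_map), period = "current")
#> <area_summary current> (x 10^4 km^2)
#>   unsuitable  3.14
#>   low         1.18
#>   medium      1.00
#>   high        1.29
#>   total       3.47

ser <- make_scenario_series(stack, list(warm = c(var1 = 0.5 * sd(v1))))
fut <- project_mean(ev, ser$stacks$warm)
change_map(binary_map(ev$mean_map), binary_map(fut), period = "current -> warm")
#> <change_summary current -> warm> expansion 1.47, retention 0.02, contraction 1.27, net +0.20 (x 10^4 km^2)

migration_vector(range_centroid(binary_map(ev$mean_map)),
                 range_centroid(binary_map(fut)), period = "current -> warm")
#> <migration current -> warm> (101.251, 31.676) -> (101.000, 30.984): 80.5 km, bearing 197.3 deg
```

Reading the numbers: the fitted model attributes ~97% of the training
gain to the true niche variable; mean held-out AUC 0.838 grades "good"
for this deliberately single-factor species; the replicate-mean map
classifies 3.47 x 10^4 km^2 as suitable; warming `var1` by half a
standard deviation relocates almost the entire >0.5 range (retention
0.02), a net gain of 0.20 x 10^4 km^2, and moves the range centroid
80.5 km toward the south-southwest (bearing 197°).

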