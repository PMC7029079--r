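---
title: "Methods: optimality models of transgenerational plasticity under climatic autocorrelation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimality models of transgenerational plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastclim)
```

## The question and the modelling stance

Whether parental (and earlier ancestral) environments should shape
offspring phenotype depends on how much information yesterday's
environment carries about tomorrow's. For an annual organism that
information lives in the *interannual* autocorrelation structure of
climate. `plastclim` implements an optimality analysis of this idea:
each candidate genotype is a fixed linear rule mapping recent
environmental deviations onto an "expected environment" (its phenotype),
fitness falls linearly with the mismatch between phenotype and realised
environment, and the winning genotype at a site is the one with the
highest geometric-mean fitness across the record — the invasion criterion
under multiplicative (fluctuating) selection. There is no mutation,
recombination or gene flow in the model: it asks which fixed strategy a
site's climate statistics favour, not how a population reaches it.

## Data model

Monthly records (long CSV: `site_id, lat, lon, year, month, ppt_mm,
tmax_c`) are aggregated to:

* **Hydrologic-year precipitation** — the total over October–September,
  labeled by the *ending* calendar year, so that winter snowpack is
  credited to the growing season it feeds. We label by the ending year
  because that is the year whose growing season the water supports.
* **Early / late season temperature** — the mean of the March–May and
  July–September monthly mean daily maxima, within one calendar year.

Years missing any window month are excluded rather than imputed: the
gridded products this pipeline is designed around are complete, so a gap
signals bad input, and imputation would leak information into the
autocorrelation estimates. Because the models need lag-consistent
(contiguous) year sequences, aggregation keeps the longest contiguous run
of complete years ending at the most recent one; anything earlier than an
internal gap is dropped and logged. At least 5 complete years are
required, and the optimisers require 8 (precipitation) or 6 (temperature).

## Descriptive statistics

For each series we report the mean, the interannual standard deviation
(IASD, the sample SD across years), the OLS trend slope (units/year), and
ACF/PACF at lags 1–12.

* **ACF estimator.** We use the "cropped Pearson" form: the lag-k value is
  the plain correlation between the first `n−k` and last `n−k`
  observations, each window standardised by its own mean and variance.
  This matches the verbal definition of a correlation "between year X and
  year X+k"; it differs from the Toeplitz-guaranteed estimator that
  divides by the full-series variance by O(1/n), which is negligible at
  the 120-year scale and documented here because the choice is not
  universal.
* **PACF.** Computed by the Levinson–Durbin recursion on the sample ACF.
  This is algebraically identical to the partial correlation obtained by
  inverting the Toeplitz correlation matrix — i.e. to "regressing out" the
  intervening lags in the correlation metric — and the test suite verifies
  the identity against that independent linear-algebra route to 1e−8 on
  random series. On short series the feasible lag range shrinks;
  infeasible lags are reported as `NA`.
* **Seasonal cross-correlations** — `cor(E_{t−1}, E_t)`,
  `cor(E_{t−1}, L_t)`, `cor(L_{t−1}, E_t)`, `cor(L_{t−1}, L_t)` and the
  within-year `cor(E_t, L_t)` — are the five "correlation classes" the
  temperature optima are later regressed on.
* Degenerate statistics (zero-variance windows) are `NA` in batch
  summaries but raise errors when the operations are called directly:
  batch runs over many sites must survive a flat site, interactive calls
  should not silently return nonsense.

## The precipitation model

A strategy `(m, g)` predicts
\[
\hat P_t = \bar P + m\,\frac{d_{t-1} + g\,d_{t-2} + g^2 d_{t-3}}{1+g+g^2},
\qquad d_k = P_k - \bar P .
\]

Design choices that were genuinely open:

* **Weight normalisation.** The multigeneration combination divides by
  `1 + g + g²`. This preserves three anchor behaviours: `g = 0` collapses
  to the single-generation rule `P̂ = P̄ + m(P_{t−1} − P̄)`; `g = 1` makes
  the three prior years contribute *equally*; intermediate `g` weights the
  parental year most. Without normalisation `m = 1, g = 1` would overshoot
  by 3×, breaking the interpretation of `m = 1` as "match the (weighted)
  past".
* **Fitness floor.** The linear cost `1 − |P̂ − P|/P̄` can reach zero or
  below when a deviation exceeds the mean (arid sites have IASD of the
  same order as the mean), which would make the geometric mean collapse or
  be undefined. We floor yearly fitness at `ε = 1e−6` (configurable in
  `(0, 0.1)`). The floor preserves the ranking among strategies that stay
  viable and is far below any fitness differences the grid search
  resolves.
* **Usable years.** Only years with a full three-year history enter the
  product (`n − 3` of `n`), so every strategy is scored on the identical
  year set. Padding the first years with shorter histories would score
  different strategies on different information.
* **Log-space product.** `W = exp(mean(log w_t))` avoids underflow across
  ~117 factors; a brute-force direct product is kept as the test oracle.
* **Grid and canonical form.** `m` on −1…1 and `g` on 0…1, step 0.1
  (21 × 11). At `m = 0` the phenotype map is independent of `g`, so
  `(0, g)` is one strategy; we canonicalise it to `(0, 0)` (221 distinct
  genotypes).
* **Tie-breaks.** Optimum: highest `W`, then smallest `|m|`, then smallest
  `g`, then lexicographic — parsimony prefers less plasticity when fitness
  ties, and output is deterministic.
* **Local maxima.** A lattice point is a local maximum when its fitness is
  ≥ all of its 8-neighbourhood; connected plateaus of equal fitness are
  merged to one representative (the flat `m = 0` column is the canonical
  case). Landscapes with ≥ 2 local maxima are "bimodal"; the package also
  exposes the analytic flag — lag-1 ACF opposite in sign to, and smaller
  in magnitude than, the mean of lag-2 and lag-3 PACF — which marks the
  correlation regimes where such bimodality arises (one optimum tracks the
  parental year with low persistence, the other leans on the grand- and
  great-grandparental years with high persistence).

## The temperature model

Strategies carry four transgenerational slopes between seasons and a
within-generation slope `w`; `w` moves only the *late* phenotype in
response to the current early season, because a phenotype cannot respond
to a cue that has not happened yet. Each of the five parameters takes
values in `{−0.2, 0, 0.1, 0.3, 0.5}` by default: a five-point set whose
full factorial is 3,125 genotypes, spanning weak negative to moderate
positive plasticity, and configurable when a finer sweep is wanted.

The mismatch cost divides by the season's long-term mean by default,
mirroring the precipitation cost. Because Celsius has an arbitrary zero
this makes absolute fitness scale-dependent (a site near 0 °C would be
punished harshly); strategy *ranking* at a site is unaffected, which is
what the optimisation uses, and a scale-free alternative (`scale =
"iasd"`, dividing by the season's interannual SD) is provided for
cross-site fitness comparisons. Usable observations are both seasons of
years 2…n (`2(n−1)` factors). Ties break by smallest total `|m|+|w|`,
then lexicographically.

## Raw versus residual variants

The residual variant removes the OLS linear trend from each series
(per season, for temperature) *preserving the mean*, so the baseline
phenotype `P̄` is identical across variants and the contrast isolates the
trend's contribution. Under a directional trend the recent past is
informative about the near future simply because both sit on the same
ramp, so raw-variant optima carry more positive parental effects; the
package exposes the per-site raw-minus-residual deltas.

## The synthetic climate generator

The generator stands in for a gridded observational product and is
first-class, tested code:

* **Annual series** are Gaussian AR(p) deviations *parameterised by their
  PACF* (the reflection coefficients), converted to AR coefficients by the
  Levinson–Durbin step-up recursion. Any `|φ_kk| < 1` gives a stationary
  model, and the bimodality condition is stated directly in lag-1 ACF and
  lag-2/3 PACF terms, so tests can dial exactly the quantities the theory
  speaks about (lag-1 PACF = lag-1 ACF). The innovation SD is
  `sd · √∏(1−φ_kk²)`, so the marginal SD equals the requested IASD
  exactly in expectation. A 200-step burn-in removes the initialisation
  transient. Trends are added centred, preserving the mean.
* **Seasonal pairs** follow a VAR(1) on (early, late) deviations with an
  innovation correlation for the within-year channel; components are
  rescaled to the requested marginal SDs (rescaling preserves all
  correlations). Stationarity (spectral radius < 1) is enforced.
* **Disaggregation to monthly records** distributes each annual value
  across its window (random seeded shares for precipitation, zero-mean
  offsets for seasonal means) so the aggregation code can be tested by
  exact round-trip.
* **Panel defaults** reproduce the continental-scale summary statistics
  the analysis context reports: precipitation mean 763 mm (cross-site SD
  443), IASD 145 mm (SD 76), lag-1 ACF centred on 0.04 (SD 0.09); spring
  10.4 °C with IASD 1.2, summer 21.2 °C with IASD 0.9 and summer–summer
  lag-1 coupling centred on 0.24 (SD 0.12). Site parameters are drawn once
  per site from those distributions (clamped to stationary ranges), and
  every series is a deterministic function of the master seed.

What the generator does *not* emulate: spatial correlation between sites,
non-Gaussian/heavy-tailed anomalies, long-memory ("pink") spectra, and
observational error. A green test therefore establishes that the pipeline
recovers structure from a correctly specified stationary Gaussian world —
not that real climate satisfies those assumptions.

## Numerical and degenerate-input choices

* Geometric means in log space; floors as above.
* Grid values are rounded to 10 decimals before comparison so `seq()`
  float drift cannot split lattice points.
* Local-maximum comparisons use a 1e−12 tolerance; fitness ties at that
  tolerance are broken by parsimony.
* Constant series: fitness 1 for every strategy at the operation level
  (zero deviations), but batch pipelines emit an in-band skip row
  (`skip_reason`) because every strategy ties and a summary would be
  meaningless; zero-variance statistics are `NA` in summaries.
* White-noise behaviour of the optimiser is length-dependent: the
  in-sample optimum of an L1-type criterion almost never lands exactly on
  `m = 0` when sampling noise in the lag-1 ACF (≈ `1/√n`) is comparable
  to the 0.1 grid step, so "no plasticity wins under white noise" is
  tested at `n = 2000`, where noise is below half a grid step. At the
  119-year scale, white-noise sites scatter their optima over `±0.1–0.2`
  — worth remembering when interpreting real-data optima maps.

## Verification design

Every load-bearing computation has an independent oracle in the test
suite: brute-force window sums for the hydrologic aggregation, naive
direct-product geometric means (to 1e−12), Toeplitz-inverse partial
correlations for the PACF (to 1e−8), `stats::arima.sim`/`stats::pacf` for
the generator's autocorrelation targets, and hand-evaluated phenotype
values for both reaction norms. Property-style acceptance tests check the
pipeline-level claims: the optimiser's `m` tracks a generated AR(1)
coefficient (within ±0.1 in ≥ 90% of seeds at n = 2000), mean optimal `m`
is strictly increasing in the generating coefficient at the 119-year
scale, generated bimodality-condition sites show multiple local maxima
far more often than condition-violating sites, detrending lowers mean
optimal plasticity under an injected positive trend, and the temperature
optimiser attributes fitness to the specific coupling channel that
generated the data. `scripts/acceptance.R` recomputes all of these from
scratch against the installed package and emits them as JSON.

## Known limitations

* The fitness cost is linear and symmetric in the mismatch; asymmetric
  costs (drought vs. flood) are out of scope.
* No cost of plasticity itself: a strategy pays only for mismatch, so the
  parsimony tie-break is the only pressure toward `m = 0`.
* The temperature model is lag-1 only (no multigeneration persistence),
  and the precipitation model is annual only (no seasonal split).
* Optima are in-sample: the same record selects and scores the strategy.
  At 120 years this overfits roughly one grid step of plasticity, as the
  white-noise analysis above quantifies.
* The taxonomy of precipitation strategies exposed by
  `classify_strategy()` (sign × persistence, 7 labels) is a deliberate
  simplification of richer classifications that depend on unavailable
  details.
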