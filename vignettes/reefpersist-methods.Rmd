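---
title: "Land–sea drivers of coral reef trajectories, heatwave response and persistence: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land-sea drivers of coral reef trajectories: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefpersist)
```

## The problem

Coastal coral reefs sit at the receiving end of two management domains
that rarely talk to each other: land (wastewater, nutrient and sediment
loading, urban runoff) and sea (fishing pressure on herbivorous fish).
`reefpersist` implements a three-stage statistical pipeline that links
annual, spatially resolved land–sea driver layers to reef outcomes
around a marine heatwave:

1. **Pre-disturbance trajectories** — which local conditions separate
   reefs whose coral cover was rising from those where it was falling.
2. **Heatwave response** — which drivers modified relative coral-cover
   loss through a severe thermal-stress event.
3. **Post-disturbance persistence** — which drivers predict whether a
   reef holds high, moderate or low reef-builder cover (hard coral plus
   crustose coralline algae) several years later, and what combined
   land–sea management scenarios imply for those probabilities.

Because the pipeline is meant to be verifiable without any particular
survey dataset, the package ships a seeded synthetic coastline generator
whose outcome structure is created from *known, injected* effects. Every
stage can therefore be tested for parameter recovery, not just for
running without error.

## Driver layers

Drivers live on a 100-m alongshore lattice (one cell = 1 ha). The
choices that matter:

* **Fish biomass** uses the allometric conversion $W = a\,\mathrm{TL}^b$
  (grams, cm) summed over observations and scaled to kg ha\(^{-1}\).
  The default survey area is a 25 m × 5 m belt (125 m²); the width is a
  configurable convention, since only transect length is standard.
* **Coastal dispersal** of land-based loads uses a Gaussian kernel
  $w(d) = \exp(-d^2 / 2\sigma^2)$ with $\sigma = 2000/3$ m, so that
  $w(2\,\mathrm{km}) = e^{-4.5} \approx 0.011$ — a plume that
  effectively vanishes at 2 km. $\sigma$ is configurable. The kernel is
  applied per source without renormalization: a receiving cell at the
  entry point sees the full load. Total delivered mass therefore grows
  with the number of receiving cells; ratios between cells, which are
  what the standardized analyses consume, are unaffected.
* **Wastewater** counts only sources within a one-year groundwater
  travel time (an input flag); loads route to the nearest shoreline cell.
* **Nutrients** add a golf-course term: area × 585 kg ha\(^{-1}\)
  yr\(^{-1}\) application × 32% leaching, attenuated inland by the same
  Gaussian form with its own scale (default 1 km) — the inland-decay
  scale is a documented stand-in, as only "reduction with distance
  inland" is specified anywhere.
* **Sediment** scales a long-term mean load by an approximate ratings
  curve $(Q_t/\bar Q)^\beta$ (default $\beta = 1.5$, configurable),
  rescaled to preserve the long-term mean; reef-level summaries use
  top-event means (top 5 pre-disturbance, top 3 in later windows).
* **Summer SST statistics** use a 90-day window centred on the day of
  the maximum 7-day moving mean (earliest day on ties; windows truncate
  at series bounds and the truncation is flagged).
* **DHW** follows the NOAA Coral Reef Watch convention: hotspots of at
  least 1 °C above the maximum monthly mean accumulate over a trailing
  84-day window, divided by 7. Adding a constant to both series and
  climatology leaves DHW unchanged, which the tests assert.
* **Wave exposure** is the mean of daily maxima at or above the year's
  97.5th percentile. "Mean of the top 97.5%" is ambiguous; the
  extreme-tail reading is implemented and flagged here.
* **Percentile convention**, package-wide: linear interpolation between
  order statistics (R type 7), including its inverse in
  `percentile_of()`.
* **Gear restrictions** map regulation flags to the six-level ranking
  (full no-take … open access). Only the six canonical combinations are
  rankable; anything else errors rather than guessing an order.

## Stage 1: trajectories

Reefs are classified positive/negative/no-change by whether cover
changed by more than 3 percentage points between the first and last
pre-disturbance survey — the cutoff mirrors the range of mean cover over
a stable decade. Group contrasts per factor use the drop-one jackknife
after removing values outside median ± 2 SD. The formal test is a
one-factor PERMANOVA on Euclidean distances of z-scored factors, with
unrestricted permutations and the +1 tie convention; when the number of
distinct two-group label arrangements is at most 20,000 the p-value is
computed by exhaustive enumeration instead. CAP (principal coordinates
followed by linear discriminant analysis on the first $m$ axes, with $m$
chosen by leave-one-out allocation success) provides the constrained
one-axis visualization and a distinctness measure. The leave-one-out
re-estimates the discriminant, not the PCO embedding — the standard
approximation at these sample sizes.

## Stage 2: heatwave response

The response is the percentage difference
$\Delta = (A_a - A_b)/A_b \times 100$, which puts reefs with different
starting cover on a common scale; reefs with zero pre-event cover are
excluded and logged. Predictor preparation is deliberately mechanical
and fully logged: the ±2 SD-of-median outlier rule with a 25% retention
band (a flagged value within 25% of the most extreme unflagged value is
kept); square-root transforms for right-skewed loads and a fourth-root
for sediment; z-standardization; iterative pruning of pairs with
$|r| > 0.7$ honouring a hypothesis-driven keep-list (heat stress over
SST mean/variability, peak over annual rainfall, phytoplankton over
irradiance, guild biomasses over total herbivore).

Models are Gaussian additive mixed models fitted with `mgcv`: penalized
cubic regression splines limited to 4 knots per predictor, a coast-
section random intercept, and REML smoothness selection. Coast sections
come from average-linkage clustering of alongshore positions: a
pronounced inflection of the intragroup-variance curve (a many-fold
drop, log-curvature > 2) sets the granularity outright; otherwise the
granularity closest to a 10-km mean span is used.

All predictor subsets up to five terms are fitted and ranked by
AICc $= -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$ the *effective* number
of parameters (summed smooth EDF plus scale) — a deliberate choice,
since penalized fits have no fixed parameter count. Akaike weights,
ΔAICc ≤ 2 top sets, and per-predictor relative importance (summed
weights of models containing the predictor) follow standard multimodel
inference. Prediction curves average the top models in prediction space
with Akaike weights (coefficient-space averaging is ill-defined across
smooths of different subsets); unweighted averaging is available. The
80% interval combines within-model variance and between-model spread.

## Stage 3: persistence and scenarios

Reef-builder cover is categorized by its 25th/75th percentiles (low ≤
25th, high ≥ 75th). The proportional-odds model is written
$$\mathrm{logit}\,P(y \le j) = C_j - \textstyle\sum_k B_k z_{k},$$
so a positive coefficient favours *higher* categories — the convention
under which "more scrapers, less wastewater → more reef builders" reads
naturally. Indexing categories from the top instead (j = 1 = high, as
the cumulative-odds equation is sometimes written) yields identical
probabilities with intercepts $C'_j = -C_{J-j}$ and the *same* slopes;
the tests verify the equivalence numerically. Estimation is in-package:
BFGS on the negative log-likelihood with analytic gradient, an
ordered-intercept reparameterization $C_2 = C_1 + e^\gamma$, relative
tolerance $10^{-12}$, covariance from the inverse observed information
(delta method back to natural parameters), and explicit failure on
separation. The fit matches `MASS::polr` to ~10⁻⁵ on shared fixtures,
but the in-package estimator is the implementation, with `polr` serving
only as an independent cross-check.

Diagnostics: Brant's Wald test of the parallel-regression assumption
(separate binary logits per cut-point with the Brant cross-model
covariance), a likelihood-ratio test at α = 0.05, and McFadden's pseudo-
R² ($1 - \ell_{\mathrm{full}}/\ell_{\mathrm{null}}$). The dredge caps
candidates at four predictors, reflecting the lower replication of this
stage, and records per-model pseudo-R² and Wald z-tests.

The scenario engine takes raw lever values (e.g. scraper biomass in
kg ha⁻¹, wastewater effluent in l ha⁻¹ yr⁻¹), pushes them through the
recorded transform and standardization chain, holds all other predictors
at their sample mean (standardized zero), and reports the three category
probabilities and fold changes between scenarios. Default anchors in the
pipeline are the 92nd/36th percentiles for scraper biomass and 95th/36th
for wastewater, mirroring how management targets are usually anchored to
observed distributions.

## The synthetic generator

The generator is first-class, tested code that defines the study
conditions:

* **Layout**: a configurable number of 100-m cells (default 200) with
  reefs (default 55) at distinct cells; point sources and impervious
  surface cluster around a few "towns" so land-based drivers vary
  alongshore.
* **Loads** are log-normal (right-skewed, like real effluent and runoff
  distributions); **rainfall** is gamma with a winter-wet seasonal
  cycle; **SST** is an annual sinusoid (base 25.95 °C, amplitude
  1.25 °C) plus AR(1) noise (φ = 0.8, σ = 0.15 °C) plus a 90-day boxcar
  anomaly of 2.2 °C in the heatwave year. With these defaults the
  heatwave year's maximum 7-day mean sits ≈ 2.2 °C above the other
  years' and peaks near 29.4 °C, and every reef far exceeds the 8-DHW
  severe-bleaching threshold — the regional conditions the pipeline is
  meant to operate under. None of the distributional forms claim the
  real region's parameters; they are stand-ins with the right shape.
* **Outcomes** realize three known structures on standardized drivers:
  a linear pre-disturbance cover slope, a heatwave percentage-difference
  response, and a proportional-odds category draw with configurable
  intercepts and slopes (default C = (−1, 1.5), B = (+1.2 scraper,
  −1.0 wastewater) — chosen so that the combined-lever scenario's fold
  change in P(high) lies in the three-to-six range by closed form).
  Covers are simulated on the percent scale and clipped to [0, 100];
  clip counts are recorded in the truth object.
* **Seeding**: one global integer seed feeds a hierarchical
  stream-per-table scheme, so identical configs give byte-identical
  bundles and individual tables are independently reproducible.

What passing tests on synthetic data do *not* show: robustness to
observation error in the drivers themselves, to spatially autocorrelated
residuals beyond the section intercept, to non-logistic category
generation, or to the survey-design quirks of real monitoring programmes
(unbalanced revisits, method calibration). The generator draws drivers
with idealized independence structure; real land-based drivers are more
collinear, which is why the pruning step exists at all.

## Numerical choices and degenerate inputs

* Exact permutation enumeration for two groups up to 20,000
  arrangements; sampled permutations with the (count + 1)/(n + 1)
  convention otherwise.
* Zero within-group distance variance makes pseudo-F unbounded and is
  an explicit error, as are empty outcome categories, constant
  predictors inside model subsets, all-zero discharge, and coincident
  25th/75th percentiles.
* On very short synthetic coasts a driver can be constant across reefs
  (the 10-km urban-runoff window swallows the whole coast); the
  generator drops such drivers from the injected-effect combination and
  records the fact rather than standardizing a constant.
* AICc candidates with $n - k - 1 \le 0$ are skipped and logged, never
  silently fitted.

## Problem sizes

The shipped tests and the acceptance script run the pipeline at the
study's own scale: 55 reefs over 20 years for the end-to-end runs;
recovery simulations use 100 replicates at n = 55 (ordinal stage,
five candidate predictors) and n = 80 (additive stage, five candidate
predictors), 1,000 null datasets with 199 permutations each for
PERMANOVA validity, and a 2,000-reef draw for the category-frequency
convergence check. These sizes were chosen to give the Monte-Carlo
assertions comfortable margins at the tolerances stated in the tests.

## Known limitations

* One grouping factor only in PERMANOVA; no nested or multi-factor
  designs, no non-Euclidean dissimilarities.
* No spatial structure beyond the coast-section random intercept; no
  interaction terms in either model stage.
* No partial-proportional-odds fallback when the Brant test rejects —
  the test reports, the analyst decides.
* The dispersal kernel treats alongshore and offshore distance with one
  scale and does not conserve mass; hydrological routing is
  nearest-shoreline-point only.
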