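# reefpersist

Land–sea drivers of coral reef trajectories, heatwave response and
persistence.

Coral reefs are shaped simultaneously by land-based human impacts
(wastewater pollution, nutrient loading, urban runoff, sediment), by
sea-based ones (fishing pressure on herbivorous fish), and by marine
heatwaves that trigger mass bleaching. `reefpersist` is for reef
ecologists and coastal resource analysts who want to quantify which of
these levers matter at which point in a disturbance cycle — and what
pulling them together, rather than in isolation, would buy.

The package builds 17 annual per-reef driver layers on a 100-m coastal
lattice and links them to reef outcomes in three stages:

1. **Pre-disturbance trajectories** — classify reefs whose coral cover
   rose or fell by more than 3 percentage points, contrast their local
   conditions with drop-one jackknife intervals, and test group
   separation with a one-factor PERMANOVA (pseudo-*F* on Euclidean
   distances of z-scored factors, exact enumeration when feasible) and
   canonical analysis of principal coordinates (CAP) with leave-one-out
   allocation success.
2. **Heatwave response** — model the percentage-difference response
   Δ = (A_a − A_b)/A_b × 100 with penalized-spline additive mixed
   models (≤ 4 knots, coast-section random intercept), rank all
   predictor subsets of size ≤ 5 by AICc, and report Akaike weights,
   ΔAICc ≤ 2 top sets, per-predictor relative importance and
   model-averaged curves with 80% intervals.
3. **Post-disturbance persistence** — categorize reef-builder cover
   (hard coral + crustose coralline algae) by its 25th/75th
   percentiles and fit proportional-odds ordinal regressions by
   maximum likelihood,
   `logit P(y ≤ j) = C_j − Σ B_k z_k`, with Brant and likelihood-ratio
   tests of the parallel-regression assumption, McFadden pseudo-R²,
   an AICc dredge (≤ 4 predictors), and a management scenario engine
   that converts raw lever settings (kg ha⁻¹ of scraper biomass,
   l ha⁻¹ yr⁻¹ of wastewater) into category probabilities and fold
   changes.

A seeded synthetic coastline generator (`synth_config()`,
`generate_coast()`, `generate_outcomes()`) creates every raw input the
driver layers consume — log-normal loads, gamma rainfall, sinusoid +
AR(1) sea surface temperature with a 2.2 °C boxcar heatwave anomaly
peaking near 29.4 °C — and draws reef outcomes from known injected
effects, so every stage is testable for parameter recovery.

## Worked example

```r
library(reefpersist)
cfg <- run_config(seed = 1, n_perm = 999)  # default synthetic study scale
res <- run_pipeline(cfg)
print(res)
#> reefpersist pipeline result; stages: simulate -> drivers -> trajectory -> heatwave -> persistence -> scenarios
#> PERMANOVA (one factor, Euclidean): pseudo-F1,40 = 6.141, P = 0.001 (sampled, 999 permutations)
#> heatwave: 219 candidate models, top importance: urban_runoff, chla, fish_scraper
#> persistence: top model [fish_scraper + wastewater_effluent], McFadden R2 = 0.245
#> scenario fold change (high): combined_vs_sea 6.85, combined_vs_land 4.15
```

The PERMANOVA line says positive- and negative-trajectory reefs occupy
distinct regions of driver space (pseudo-F₁,₄₀ = 6.14, permutation
P = 0.001). The heatwave dredge fitted 219 candidate additive models;
the drivers the generator actually injected (urban runoff, phytoplankton
biomass, scraper biomass) come out with the highest relative importance:

```r
round(res$heatwave$importance, 2)
#>        urban_runoff                chla        fish_scraper         fish_grazer
#>                1.00                1.00                0.89                0.52
#>      sediment_input          fish_total wastewater_effluent             dhw_max
#>                0.51                0.18                0.16                0.11
```

The persistence stage recovers the injected ordinal truth (scraper
+1.2, wastewater −1.0) as the AICc-top model, and the scenario engine
turns percentile-anchored lever settings into category probabilities:

```r
res$scenarios$result
#> Scenario category probabilities:
#>             low moderate  high
#> initial   0.780    0.209 0.011
#> combined  0.030    0.412 0.559
#> sea_only  0.304    0.615 0.082
#> land_only 0.199    0.666 0.135
```

A reef with low scraper biomass and high wastewater ("initial") is most
likely in the low reef-builder category (78%); managing sea or land
alone helps modestly; managing both together lifts P(high) to 56% —
a 6.9-fold and 4.2-fold gain over the single-lever scenarios.

See `vignette("reefpersist-methods")` for the models, their assumptions
and the design decisions (kernel scale, window conventions, AICc with
effective parameters, section clustering, scenario anchors).

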