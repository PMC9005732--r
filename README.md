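# afforwet

Quantifying the trade-off between tree planting and wetland conservation.

Afforestation raises evapotranspiration (ET) and lowers runoff (Q) and soil
moisture (SM); at catchment scale that reduction in available water shrinks
wetlands, and it does so far more in dry climates than in wet ones.
`afforwet` is an R package for ecohydrologists and conservation analysts
that implements the full analysis chain behind this question as tested,
reusable, tidyverse-style functions:

* **Budyko water-balance attribution.** Annual P splits into ET and Q as a
  function of the aridity index φ = PET/P and a plant-available-water
  coefficient *w* (forest *w* = 2, grass *w* = 0.5):

  ET/P = (1 + wφ) / (1 + wφ + φ⁻¹),  Q/P = φ⁻¹ / (1 + wφ + φ⁻¹),

  and the runoff change from converting a fraction Δf of a cell from grass
  to forest is δQ = P · Δf · [Q/P(φ, w_f) − Q/P(φ, w_g)].
* **A TOPMODEL-style wetland diagnostic.** A sigmoid of the soil-moisture
  deficit D = SM_sat − SM maps each cell to its saturated (wetland)
  fraction, f(D) = f_max (1 + v·e^{k(D−d0)})^{−1/v}, with static
  (max-extent map) and dynamic (annual-maximum series, bounded nonlinear
  least squares) calibration.
* **Factorial attribution and sensitivity decomposition.** S1 − S0
  (with/without forest change) isolates the planting signal, and
  δA_wet/δA_forest = (δA_wet/δSM) × (δSM/δA_forest) splits it into the
  hydrologic and the wetland response, summarised by climate zone
  (wet φ < 1, mesic 1–2, dry > 2) with the 1 % wetland-cell rule, the 10 %
  rice exclusion and a 5th–95th percentile outlier screen.
* **Planting scenarios and basins.** Four near-term allocation rules
  (historical-trajectory SA and zone-targeted SA_dry / SA_mesic / SA_wet),
  projection through a bucket soil-moisture surrogate, loss histograms
  (2–4 / 4–6 / 6–8 / 8–10 / >10 %), basin aggregation, protection-level
  regressions and exceedance counts.
* **A synthetic-data module** generating climate, forest histories, soil
  moisture, noisy wetland observations, basins and rice masks with known
  ground truth, so calibration and attribution are verifiable end to end.

## Worked example

```r
library(afforwet)
library(dplyr)

study  <- gen_study(seed = 42)                       # 200 cells, PET/P 0.3-3
attrib <- historical_attribution(study, study$truth) # S1 - S0 chain
sens   <- sensitivity_ratios(attrib$changes)

screened <- filter(sens, included) |>
  group_by(zone) |>
  group_modify(~ .x[.x$dawet_daforest %in% drop_outliers(.x$dawet_daforest)$values, ]) |>
  ungroup()
zone_box_stats(screened, dawet_daforest)
#> # A tibble: 3 × 10
#>   zone      min      q20      q40       q50       q60      q80      max     mean
#>   <fct>   <dbl>    <dbl>    <dbl>     <dbl>     <dbl>    <dbl>    <dbl>    <dbl>
#> 1 wet   -0.0240 -0.00253 -0.00118 -0.000477 -0.000415 -8.60e-5  0       -0.00263
#> 2 mesic -0.137  -0.0664  -0.0282  -0.0176   -0.0127   -6.34e-3 -7.62e-4 -0.0340
#> 3 dry   -0.156  -0.111   -0.0846  -0.0693   -0.0524   -3.65e-2 -7.01e-3 -0.0731
```

Each row is a climate zone; the values are wetland-area change per unit
forest-area change (km² per km² planted) across that zone's usable cells
after the percentile screen. The mean sensitivity strengthens from
−0.003 km²/km² in the wet zone to −0.073 km²/km² in the dry zone: a planted
square kilometre costs ~25× more wetland where PET/P > 2 — the trade-off
the package is built to expose.

The whole chain (inputs → calibration → attribution → scenarios → basins)
runs in one call:

```r
run_pipeline(run_config(seed = 42))
#> <pipeline_report>
#>   cells: 200  included in sensitivity: 137
#>   national attributed loss by scenario (km2):
#>     SA         918.36
#>     SA_dry    1539.39
#>     SA_mesic   909.04
#>     SA_wet      11.00
```

Equal national planting targets placed in different zones end very
differently: concentrating the plan in the dry zone roughly quintuples the
attributed wetland loss relative to planting in the wet zone.

## Documentation

The methods vignette
(`vignettes/afforestation-wetland-tradeoff.Rmd`) documents the models, the
parameter defaults and the reasoning behind them, every threshold and
boundary convention, what the synthetic generator does and does not
emulate, and known limitations.
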