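---
title: "Afforestation–wetland trade-off analysis: models, conventions, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Afforestation–wetland trade-off analysis: models, conventions, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afforwet)
library(dplyr)
```

# The problem

Large-scale tree planting raises evapotranspiration (ET) and lowers runoff
(Q) and soil moisture (SM). At catchment scale that reduction in available
water starves wetlands, so national planting programs carry a conservation
trade-off that is sharpest where the climate is dry. `afforwet` packages the
analysis chain needed to quantify this trade-off: a Budyko water-balance
attribution of runoff change to forest-cover change, a soil-moisture-deficit
diagnostic of subgrid wetland fraction with two calibration modes, factorial
(S1 − S0) attribution, a sensitivity decomposition by aridity zone, planting
scenario projection, and basin-level conservation statistics — all
exercisable end to end on synthetic gridded data with known ground truth.

# Budyko partitioning and runoff attribution

Annual precipitation P splits into ET and Q as a function of the aridity
index $\phi = \mathrm{PET}/P$ and a plant-available-water coefficient $w$:

$$\frac{ET}{P} = \frac{1 + w\phi}{1 + w\phi + \phi^{-1}}, \qquad
  \frac{Q}{P} = \frac{\phi^{-1}}{1 + w\phi + \phi^{-1}}.$$

The two expressions share a denominator, so their sum is exactly 1 — a
property the test suite asserts to $10^{-12}$ across a dense $(\phi, w)$
sweep. Deep-rooted forest holds more plant-available water than grass, so
the package defaults are $w_f = 2$ and $w_g = 0.5$. Converting a fraction
$\Delta f = f_t - f_{t-1}$ of a cell from grass to forest changes runoff by

$$\delta Q = P \, \Delta f \left[\, Q/P(\phi, w_f) - Q/P(\phi, w_g) \,\right],$$

which is negative (runoff loss) for any forest gain. $|\delta Q|/P$ as a
function of $\phi$ is unimodal with an interior maximum near $\phi \approx 1$;
for a 20 % forest gain it exceeds 2 % of annual precipitation throughout
$\phi \in [0.6, 2.2]$ — the mesic-to-dry band where afforestation bites
hardest. `grid_delta_runoff()` applies the relation per cell-year using each
year's P and, by default, the cell's *climatological* $\phi$ (an `"annual"`
option exists); the default matches the convention of driving the curve with
the long-term aridity while accumulating with per-year precipitation.

# The bucket soil-moisture surrogate

A full land-surface model is out of scope here; the package instead declares
a deliberately simple monthly bucket per cell,

$$SM_{t+1} = \mathrm{clamp}\left(SM_t + P_t - ET_t - Q_t,\ 0,\ SM_{sat}\right),$$

with $ET_t = (ET/P)_{\mathrm{Budyko}} \cdot P_t \cdot SM_t / SM_{sat}$ and
linear drainage $Q_t = d\,SM_t$. The evaporative fraction uses the cell's
climatological aridity and an **effective** coefficient
$w = f\,w_f + (1-f)\,w_g$ mixed linearly by forest fraction, so planting
trees raises ET and dries the bucket monotonically — the single causal
pathway the attribution machinery is designed to detect. Parameters, with
the reasoning behind the defaults:

* `sm_sat = 300` mm — a typical root-zone available-water capacity for a
  ~2 m soil column.
* `drainage = 0.1` month⁻¹ — slow enough that humid cells (low $\phi$)
  accumulate to saturation. This is deliberate: it puts wet-zone cells at
  zero soil-moisture deficit, which is what makes their wetlands insensitive
  to further forcing (below).
* flat 1/12 monthly split of annual P and PET — seasonality is irrelevant
  to annual-maximum statistics under a flat split, so it is the default; a
  sinusoidal option (`seasonal_amplitude`) exists but defaults off.
* clamping at 0 and `sm_sat` resolves the budget at the extremes; the exact
  budget identity $\Delta SM = P - ET - Q$ is asserted (machine tolerance)
  on every unclamped step, and clamped steps are flagged in the output.

# The wetland diagnostic

TOPMODEL reasoning links a grid cell's saturation deficit to the fraction of
its area that is saturated, through the CDF of the topographic index. The
package does not refit that CDF from topography; it adopts a generalized
sigmoid of the monthly soil-moisture deficit $D = SM_{sat} - SM$:

$$f(D) = f_{max}\left(1 + v\,e^{k (D - d_0)}\right)^{-1/v},$$

with attainable maximum $f_{max}$, sensitivity $k$ (mm⁻¹), half-saturation
deficit $d_0$ (mm) and asymmetry $v$ (default 1 = symmetric logistic, where
$f(d_0) = f_{max}/2$). The sigmoid has the right shape (CDF-like,
saturating, strictly decreasing in $D$), is invertible for static
calibration, and keeps the parameter count identifiable from ~16 annual
maxima. Defaults $k = 0.1$ mm⁻¹ and $d_0 = 85$ mm place the steep limb at
the deficits the bucket produces in dry cells while wet cells (deficit near
0) sit on the flat plateau — encoding the mechanism that wetlands in dry
climates respond strongly to drying while saturated ones barely respond.

Two calibration modes mirror the two kinds of observational product:

* **Static** (`calibrate_static()`): one long-term maximum-extent map per
  cell can identify one parameter, so the shape is held fixed and $f_{max}$
  is solved exactly so the modeled maximum (at the minimum-deficit
  timestep) reproduces the observation. The inversion is idempotent and
  cells observed at zero get $f_{max} = 0$.
* **Dynamic** (`calibrate_dynamic()`): an annual-maximum series identifies
  $(f_{max}, k, d_0)$ by bounded nonlinear least squares
  (Levenberg–Marquardt via minpack.lm), $v$ held fixed. A small
  multi-start over $k$ and $d_0$ initialisations guards against local
  minima. Identifiability needs yearly minimum deficits that actually sweep
  the limb of the sigmoid; cells with (near-)constant deficits are flagged
  unconverged rather than silently returned, as are fits that exhaust the
  iteration budget.

Monthly fractions are reduced to annual maxima before any comparison with
observations, and "wetland area" means fraction × full cell area — there is
no sub-cell lowland masking.

# Attribution and the sensitivity decomposition

The contribution of forest change is isolated factorially: S1 (with forest
change) minus S0 (identical, forest frozen at the start year). Period
changes are **end-minus-start differences** of the attributed series (a
regression-through-annual-points alternative was considered; differences
match the convention of plotting cumulative changes by year). The marginal
wetland sensitivity then decomposes along the causal chain:

$$\frac{\delta A_{wet}}{\delta A_{forest}} =
  \frac{\delta A_{wet}}{\delta SM} \times
  \frac{\delta SM}{\delta A_{forest}}.$$

Because all three ratios are built from the same period differences, the
identity is algebraically exact wherever all terms are finite; the test
suite checks it cell by cell on the seeded multi-zone domain. Cells are
excluded (flagged, with a reason, never dropped silently) when they never
had forest, had no forest change, or fail the wetland-cell mask.

## Conventions, all documented as package choices

* **Wetland grid cell**: mean annual-maximum wetland fraction > 1 %
  (strict; exactly 1 % is excluded).
* **Rice exclusion**: cells with rice coverage > 10 % are removed (strict;
  exactly 10 % is kept).
* **Climate zones**: wet $\phi < 1$, mesic $1 \le \phi \le 2$ (closed — the
  boundary values belong to mesic), dry $\phi > 2$.
* **Trend**: ordinary least squares against calendar year with a two-sided
  t-test; fewer than 3 points gives a missing result; a constant series
  gives slope 0 with p = 1.
* **Quadrants**: forest trend on x, wetland trend on y; quadrant 4
  (forest up, wetland down) is the trade-off signature; zero trends are
  `boundary`.
* **Outlier screen** (`drop_outliers()`): keep values inside the closed
  5th–95th percentile band, percentiles computed by linear interpolation of
  the empirical CDF (`stats::quantile()` type 4). Under this definition the
  5th/95th percentiles of 1…100 are exactly 5 and 95, and with two values
  the band keeps the smaller and drops the larger — so a single wild ratio
  paired with one clean cell leaves exactly the clean cell. The box
  statistics (`zone_box_stats()`) use the standard sample quantile
  (type 7), under which the median of {1,…,5} is 3 as one computes by hand.
  The two jobs use the definition natural to each; both are fixed and
  documented here.
* **Loss bins**: [2,4), [4,6), [6,8), [8,10) and strictly > 10 %. A loss of
  exactly 10 % falls in neither top bin and is counted as uncounted; gains
  are never reported as negative losses (loss 0 %, `gain` flag).

# Scenarios

Four near-term planting plans share one national target over 2017–2035 with
linear trajectories and a per-cell ceiling (`max_forest_frac = 0.9`, the
remainder reserved non-plantable). `SA` allocates proportionally to each
cell's historical planting (the plan continues the historical trajectory);
`SA_dry` / `SA_mesic` / `SA_wet` put the full target into one climate zone,
proportionally to remaining plantable area — the paper-style "extreme"
siting experiments; the within-zone rule is the package's own choice since
no standard exists. Allocation conserves the target to within 0.1 % or
fails with the shortfall reported. "Constant climate" is implemented by
seeded resampling (with replacement) of the historical years
(`recycle_climate()`); the draw is part of the scenario configuration, and
an alternate climate realisation can be supplied directly. Each projection
runs the bucket + diagnostic chain under the scenario and under a
constant-forest control, attributes S1 − S0, and reports losses relative to
the control-run mean annual-maximum extent — the extent the start-of-window
forest map would have maintained. A zero-target scenario is bit-identical
to its control, so its attributed loss is exactly zero.

# Basins

Cell fields aggregate to basins exactly (sums) or by area weighting
(means); basin-scale Budyko attribution aggregates P, PET and forest cover
first and applies the runoff equation to the basin means. A basin
containing several reserves takes the **highest** protection level present.
The per-group regression of cumulative wetland change on cumulative forest
change uses ordinary least squares with an intercept (intercept handling is
a package choice) and marks significance at the 99 % level.

# What the synthetic generator does and does not emulate

`gen_study()` builds a 10 × 20-cell, 0.5° grid (200 cells of ~2,500–2,700
km², 17 years) whose column-mean aridity sweeps 0.3–3 so all three climate
zones are populated; interannual variability is multiplicative lognormal
noise (CV 0.15, the order of interannual precipitation variability in
mid-latitude East Asia); the historical forest gain defaults to 4 % of the
domain area, the order of China's relative forest expansion over 2000–2016;
basins are seeded contiguous partitions; observation products are the
diagnostic's own output plus multiplicative noise. These sizes keep the full
suite and the scenario runs comfortably small while leaving every zone with
dozens of cells.

Passing tests on this world demonstrate that the *machinery* is correct —
conservation, calibration recovery, the decomposition identity, the
qualitative dry-over-wet vulnerability ordering that the generator encodes
through the bucket + sigmoid design. They do not validate the surrogate
against a real land-surface model: real SM responds to forest change
through canopy interception, rooting depth, snow and lateral flow that the
bucket collapses into one mixed Budyko coefficient; real wetland products
carry spatially correlated retrieval errors, not independent multiplicative
noise; and the rice mask is static while real paddy extent is dynamic.
Headline area totals from the real analysis depend on those drivers and are
not reproducible here; the package's claims are about the method.

# Known limitations

* The deficit→fraction sigmoid is a stand-in for a topographic-index CDF;
  its coefficients are not comparable to any published CTI fit.
* Dynamic calibration is per cell and unregularised; with narrow deficit
  ranges the shape parameters are weakly identified (flagged, not fixed).
* No land–atmosphere feedback: precipitation never responds to planting.
* p-values carry no spatial-autocorrelation correction, matching the
  trend-map convention the analysis follows.
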