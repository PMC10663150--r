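---
title: "Estimating gridded net migration from subnational vital statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating gridded net migration from subnational vital statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Direct observations of migration flows are scarce, but births, deaths and
population counts are observed almost everywhere. The demographic balancing
equation turns this around: over an interval, population change equals
natural change (births minus deaths) plus net migration, so

$$\mathrm{netMgr}_{t} \;=\; \big(P_{t+1} - P_{t}\big) \;-\;
  \frac{P_{t}\,(b_t - d_t)}{1000},$$

where $b_t, d_t$ are crude birth and death rates per 1,000. If the rates can
be estimated on the same grid as the population rasters, net migration
becomes computable for every cell and year as a residual. `netmigr`
implements that whole chain — harmonizing raw subnational vital-rate series,
downscaling them to a grid, deriving signed net migration, delineating urban
extents, binning the world into socioclimatic strata and classifying what
migration does to local population change — together with a synthetic-world
generator whose ground truth lets every stage be verified.

## The synthetic world

`generate_world()` builds a miniature world satisfying, exactly and at every
cell-year, the bookkeeping identity
$P_{t+1} = P_t + \mathrm{births}_t - \mathrm{deaths}_t + \mathrm{netMgr}_t$.
Its study conditions (the defaults of `world_config()`) are a 64×64 grid,
8 countries in 4 income groups, 4 admin-1 units per country each split into
2 admin-2 units, years 2000–2009, and cell-level rate noise of sd 1.0 per
1,000 — roughly the signal-to-noise a subnational census series carries.
Admin units are axis-aligned rectangles nested exactly on the raster, so
zonal arithmetic has no polygon–raster ambiguity and hierarchical sums are
exact.

The base population surface is a spatially correlated log-normal field with
per-country level factors (mean ≈ 2,000 persons per 100 km² cell), which
produces realistic density gradients for the urban-extent machinery. Growth
over time is *not* imposed exogenously: it emerges from the vital rates and
the migration field through the bookkeeping identity. True rates are affine
in the same predictors the downscaling regression uses — scaled population
density, HDI, and the reproductive-women share (births) or the
age/life-expectancy ratio (deaths) — with per-income-group coefficients, so
the regression is well-specified and parameter recovery is a meaningful
test. Because scaled density itself depends on the population trajectory,
generation iterates population → covariates → rates → population to a fixed
point (relative tolerance 1e-13, typically a few dozen iterations). The true
net migration field is a smooth signed field scaled to half the local
natural-change magnitude, which keeps populations positive.

The age–sex structure is a per-cell mixture of a young pyramid (peaked in
the reproductive ages) and an old one (peaked past them), so that the
reproductive-women share and the mean age vary independently of density and
HDI. Per-admin-1 HDI levels track the income group with unit-level spread of
±0.10 — comparable to the within-country spread of real subnational HDI
tables — plus a small annual drift; that spread is what identifies the HDI
coefficients in the group-wise regressions.

What the generator deliberately does **not** emulate: realistic coastlines
or projections, cohort-component age dynamics, gross in/out flows (only the
net field exists), census measurement error beyond i.i.d. Gaussian rate
noise, and boundary-change gazetteers. Passing tests therefore demonstrate
the correctness of the estimator's arithmetic and its statistical recovery
under an in-family data-generating process — not robustness to the
out-of-family messiness of real censuses.

### Census defects

`inject_missingness()` reproduces the four defect patterns of real
subnational vital statistics, each applied to a configurable fraction of
admin-1 units:

* **combine** — the smallest-population units get implausible reported rates
  (inflated 2.5×, the classic capital-district artefact); the fix pools
  events and population with the most populous neighbour so both end up
  with the same rate.
* **split** — two adjacent units are reported as one parent before a split
  year. `apply_split_backcast()` forms the children's population-weighted
  combined rate at the first post-split year, takes each child's ratio to
  it, and applies those ratios to the parent's pre-split rates.
* **partial** — ~30% of a unit's years are blanked; `fill_partial()` scales
  the gap from the neighbour with the least absolute rate difference at the
  reference year (the closest year where both report; ties resolve to the
  earlier year).
* **absent** — all records removed; the unit inherits the national series.

The processing order is combine → split backcast → partial fill → national
fallback → interpolate/extrapolate → national bias correction: each later
stage assumes the structure the earlier ones restore. Interior gaps are
interpolated linearly in time; years outside a unit's reported range follow
the macroregion's year-over-year trend *multiplicatively*, which preserves
nonnegativity of rates (an additive trend could cross zero). Macroregional
trends are population-weighted means over countries with full coverage; the
synthetic world uses its income groups as macroregions, and region
membership is a configuration input. The final bias correction rescales
every unit-year by `reported_national / weighted_mean(subnational)`, after
which national aggregates match reported national rates to machine
precision. Whether that correction precedes or follows unit-level
interpolation is genuinely open; placing it last guarantees the national
constraint survives all other edits, which is the property downstream
stages rely on.

## Downscaling

Unit-level rates are downscaled in three steps.

**1. Income-group regressions.** One OLS fit per income group and rate
type, pooling unit-years across the whole period. Predictors are unit-level
aggregates of the gridded covariates. A genuinely open design choice is
whether that aggregation should weight cells by population; this package
fits on *population-weighted* covariate means (the default of
`downscale_rates()`; `aggregate_covariates_to_units()` also offers the
unweighted mode). The reason is internal consistency: a census rate is by
construction a population-weighted aggregate of cell-level rates, so a
cell-linear model aggregates exactly to a model linear in the
population-weighted covariate means — with unweighted means the regression
would be misspecified by construction even at zero noise.

**2. ATPK of areal residuals.** Residuals (census rate minus
population-weighted aggregate of the model's cell predictions) are
interpolated from unit centroids to cells by ordinary kriging under an
exponential-with-nugget variogram, fitted by method of moments to binned
empirical semivariances (8 bins; per-year residual fields share one
variogram since the regression pools years but residuals are
year-specific). Full deconvolution of the areal variogram to point support
is underdetermined at this problem size; instead a per-unit additive
correction enforces the testable contract directly — *coherence*: the
unweighted mean of the distributed surface over each unit equals its areal
residual (checked to 1e-6). Degenerate cases (near-zero residual variance,
fewer than 3 units, singular kriging systems) fall back to uniform
within-unit assignment, with a message. The kriging neighbourhood is capped
at 32 units for bounded cost.

**3. Mass-preserving adjustment.** Each cell's approximated rate
$R_i$ is rescaled by its unit's factor
$C_n \sum_j p_j \,/\, \sum_j R_j p_j$, so implied events match the census
exactly. Numerical edge cases: negative approximated rates are floored at 0
before adjustment; zero-population cells keep their approximated rate (they
carry no events and would otherwise absorb an undefined constraint); a unit
whose weighted approximation is zero against a positive census rate
receives the census rate uniformly.

## Net migration, urban extents, bins, classes

Net migration per cell-year is population change minus natural change, with
*start-of-interval* population converting rates to events — the same-year
convention under which the rates were harmonized. No clamping is applied:
the sign is the signal. The series necessarily ends one year before the
population record.

Urban extents are delineated per country-year by ranking cells on scaled
density (ties: raw population, then cell index) and accumulating population
until the national urban target `totPop × shr_urbanPop` is met; the
crossing cell is included. This makes the urban set monotone in the share
and accurate to one cell's population.

Socioclimatic bins are nested population-weighted deciles: 10 of HDI, each
split into 10 of aridity, numbered `10·hdi_decile + aridity_decile`
(0-based). Weighted deciles sort by (value, cell index) and assign each
cell the decile of its cumulative weight *before* inclusion, which is
deterministic under ties and yields exactly balanced bins on
quasi-continuous inputs. Bin weights use the full-period mean population,
since the binning stratifies long-term accumulated migration; the weight
year is configurable because no single choice is canonical.

The impact classifier compares window population change, accumulated
migration, and their difference (the counterfactual change without
migration) under six strict-sign criteria; the "turns" classes are
evaluated first. Because the six patterns are mutually exclusive, the order
is immaterial except for readability. Any exact zero matches no strict
inequality and falls into a seventh class, `negligible` — the
boundary-case convention this package adopts for the categorical scheme's
seventh slot. The direction classifier reads the sign pair of accumulated
urban and rural migration; exactly-one-zero patterns are reported as
`zero` with an audit subclass naming which side moved, since the criteria
use strict inequalities only.

## Problem sizes and what the checks show

The shipped analysis scripts and acceptance checks run on the default
64×64, 10-year world (4,096 cells, 32 units; generation and full pipeline
in a few seconds), with an 8×8 world for the closure identity and a
10,000-cell quasi-continuous field for bin balance. At these sizes the
verified properties are: exact closure (≤1e-12 persons), unit-level mass
conservation and national consistency to ~1e-15 relative, ATPK coherence to
~1e-16, coefficient recovery within 10% at noise sd 1.0 (typically ≤7%),
cell-rate correlations ≥0.96, and admin-1 migration recovery with
negligible error — the last because unit-level mass conservation transfers
the aggregated noise along with the signal, an exact-by-construction
property worth understanding when interpreting it as a "recovery" result.

## Known limitations

* Rasters are in-memory matrices with constant cell area; real-data use at
  global 5-arcmin scale would need block-wise I/O and geodesic areas (the
  formulas only need densities, so the structure carries over).
* The HDI/life-expectancy surfaces are painted from unit tables and
  linearly interpolated in time — a stand-in for a proper tabular-to-grid
  interpolation method.
* The kriging treats areal residuals as point data at centroids before the
  coherence correction; for very heterogeneous unit shapes a true
  area-to-area covariance model would differ within units (unit means are
  identical by construction).
* Validation machinery compares like with like on the synthetic world; it
  does not establish accuracy against real migration observations.
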