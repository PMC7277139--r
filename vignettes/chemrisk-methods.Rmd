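---
title: "Endpoint-based chronic risk assessment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endpoint-based chronic risk assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemrisk)
```

## The problem

After an accidental release of a carcinogenic chemical, acute consequence
models answer what happens in the first hours; the chronic question — how
much *long-term* cancer risk the surrounding population accrues through
soil that the plume contaminated — needs a different construction. The
workflow implemented here is:

1. **Multimedia fate.** Simulate the hourly dispersion of the released
   mass in air and its transfer to surface soil on a regular grid, driven
   by hourly meteorology.
2. **Extinction endpoint.** Find the day after which the air
   concentration never again exceeds the chemical's atmospheric
   background anywhere in the domain. That day closes the
   dose-accumulation window: exposure is counted from the accident to
   extinction rather than over an arbitrary regulatory duration, which
   avoids overestimating dose when concentrations spike and collapse.
3. **Dose and risk.** Accumulate each cell's daily soil concentration
   over the window into a lifetime average daily dose (LADD) for the
   soil-ingestion pathway per age group, convert to excess cancer risk
   (ECR) with an oral cancer slope factor, and map red/orange/green risk
   zones.

The packaged worked example is a 40-tonne, one-hour benzyl chloride leak
from a petrochemical complex starting at midnight on 1 January 2017,
simulated on a 16 km x 12 km grid of 100 m cells with a 10 m mixed layer
over 100 days.

## Air dispersion: a vertically well-mixed Gaussian-puff model

The release is discretised into puffs (default 6 per release hour), each
carrying an equal share of the emitted mass. Every hour each puff

* advects with the hour's wind — displacement `u * 3600` m toward
  `wind_direction + 180` degrees (meteorological "from" convention; a
  north-westerly, 315 degrees, transports the plume south-east);
* grows horizontally: `sigma_y` follows the Martin (1976) power-law fits
  of the Pasquill–Gifford curves as a function of cumulative travel
  distance, added in quadrature to an initial spread `sigma0` (default
  10 m, a metres-scale leak source);
* loses mass to first-order air decay and to dry deposition.

Vertically the chemical is assumed uniformly mixed through the 10 m
layer, so the concentration at a cell is

```
C(x, y) = m * 1e6 * exp(-r^2 / (2 sigma_y^2)) / (2 pi sigma_y^2 * H)
```

in mg/m³, with `m` the puff mass (kg), `r` the distance from the puff
centre and `H` the mixing height. This is the `"centre"` kernel of
`step_hour()`. The simulation driver instead uses the `"cell_mean"`
kernel — the exact integral of the Gaussian over each cell, computed as
a product of normal-CDF differences — because a young puff is narrower
than a 100 m cell and point sampling at cell centres would silently drop
most of its near-source deposition.

Three numerical choices matter:

* **Sub-hourly stepping.** `run_simulation()` splits each hour into 30
  substeps so that a 2 m/s wind moves a puff 240 m, not 7.2 km, between
  field evaluations; hourly fields are substep means.
* **Exact exponential losses.** Air decay (`k_air`, per hour) and
  deposition depletion (`v_d / H`) act as one exponential per substep.
  The reported field is the time-averaged concentration over the
  substep, which makes the soil increment formula below exactly
  mass-consistent — the hourly mass balance (released = airborne + soil
  + exported + decayed + deposited outside the grid) closes to floating
  point precision, and the test suite enforces 1 %.
* **Export buffer.** Puffs whose centre drifts more than 5 km past the
  domain edge are dropped and booked as exported; return flow at the
  default winds is negligible.

## Soil: deposition, decay, and a slow return flux

Dry deposition transfers `v_d * C` (mg/m²/s) to the surface; over an
hour a cell's soil concentration rises by `v_d * C * 3600 / (rho * d)`
mg/kg with bulk density `rho` = 1300 kg/m³ and a 1 cm mixing depth —
conventional surface-soil screening values, both configurable. The
deposition velocity defaults to 0.005 m/s. Soil decays by a first-order
rate once per simulated day.

The benzyl chloride record additionally carries a slow soil-to-air
return flux (`revolatilization_rate`, default 5e-5 per day for the
packaged chemical, zero for `chemical_properties()` in general). The
case study this package emulates reports an atmospheric rebound — air
concentrations above background long after the primary plume left —
which is only possible if contaminated soil returns mass to the air; the
mechanism is not described, so the simplest mass-closed realisation is
used: each hour a first-order fraction of each cell's soil inventory
enters that cell's air column as a ventilation-limited concentration
(scaled by the ratio of the cell transit time `dx / u` to the hour) and
is then carried out of the domain without re-deposition. It is a
screening construction: it sustains a realistic secondary air signal and
therefore a realistic extinction time, but its magnitude should not be
over-interpreted.

### Parameter anchoring for benzyl chloride

| parameter | value | basis |
|---|---|---|
| molecular weight | 126.58 g/mol | formula mass of C₇H₇Cl |
| oral cancer slope factor | 0.17 per mg/kg-day | US EPA IRIS |
| atmospheric background | 0.01 ppb | literature ambient level |
| air decay | 0.02 h⁻¹ | OH-radical reaction lifetime ≈ 2 d |
| soil decay | 0.027 d⁻¹ | late-time decline of the reported soil maximum (days 10–99), where decay is the only active process; the faster early decline reflects deposition-phase redistribution |
| deposition velocity | 0.005 m/s | mid-range screening value for a reactive gas |
| re-volatilization | 5e-5 d⁻¹ | calibrated so the secondary air signal extinguishes on the ~100-day timescale the case study reports (the seed-1 packaged run reaches extinction on day 98) |

## The extinction endpoint

`ppb_to_mg_m3()` converts the background (0.01 ppb ≈ 5.18e-5 mg/m³ for
benzyl chloride at 25 °C / 1 atm, molar volume 24.45 L/mol, both
configurable) and `determine_endpoint()` applies the rule: the endpoint
is the **last** day on which any cell's daily-average air concentration
strictly exceeds background. Last-exceedance rather than first-crossing
matters because the secondary return flux makes the daily grid maximum
non-monotone — a first-crossing rule would close the window at the early
dip and discard most of the accumulated dose. On strictly decreasing
series the two rules coincide (a property the tests check). Equality to
background counts as extinct. If even the final simulated day exceeds
background the function raises a `chemrisk_horizon_error` instead of
returning a truncated window: the honest remedy is a longer horizon.

## Dose and risk

For one cell and one age group,

```
LADD = sum(n = 1..endpoint_day) C_soil[n] * IR_soil / (BW * LT)   [mg/kg/d]
ECR  = LADD * CSF
```

where `IR_soil` is the soil intake rate, `BW` body weight and `LT`
lifetime in days. The denominator is the product `BW * LT` — the only
reading that yields a lifetime-averaged daily dose with correct units.
The packaged exposure-factor table uses soil intake 80 mg/d for ages
0–18 and 40 mg/d for adults, body weights 13.3 / 53.6 / 63.3 / 60.7 kg
for the 0–9, 10–18, 19–65 and >65 groups, and a shared life expectancy
of 30,186 days. Because the groups share `LT` and the equations are
linear, two groups' ECR fields on the same history differ by the exact
scalar `(IR_a/BW_a) / (IR_b/BW_b)` — the cross-group consistency the
acceptance checks exercise.

Zones: red at ECR ≥ 1e-6 (ties at the limit are red — the
safety-conservative reading of "at the acceptable-risk limit or
higher"), orange in [1e-7, 1e-6), green below. Summary statistics are
taken over **all** grid cells, including the unaffected majority; the
green percentage is computed as the exact complement
`100 - red - orange` so the three shares always partition 100.
Percentages are rounded half-up to two decimals only at report time
(`tidy()`); internal values are unrounded. Skin-contact and inhalation
pathways are excluded by construction: the method assesses the chronic
soil-ingestion route only.

## The synthetic meteorology generator

No observed weather series ships with the package;
`generate_synthetic_meteo()` emulates an hourly archive with three
independent draws per hour:

* direction: wrapped normal around a prevailing direction (default 315
  degrees, spread 30 degrees);
* speed: normal truncated at zero via the inverse CDF (default mean 2
  m/s, sd 1 m/s — light winds typical of a coastal industrial basin);
* stability: categorical over Pasquill classes A–F with weights
  (0.03, 0.07, 0.15, 0.35, 0.20, 0.20) — a neutral-dominated
  climatology in which the stable classes E–F occupy roughly their
  nocturnal share of hours.

What it deliberately does **not** emulate: diurnal and synoptic
autocorrelation (every hour is independent), sea–land breeze rotation,
calms with meander, precipitation and humidity. Consequences worth
knowing: deposition is effectively finished within the first day
(whereas persistence and recirculation would spread it over days), and
the hour-1 stability/speed draw — hence the near-source soil peak — is
seed-sensitive. With the packaged configuration (seed 1) the 100-day
example reaches extinction on day 98; some seeds do not reach extinction
within 100 days and raise the designed horizon error. Passing tests on
this generator demonstrate the *method's* correctness and the model's
qualitative behaviour, not agreement with any real wind record.

## Problem sizes used in the checks

The test suite runs the full packaged scenario (160 x 120 cells, 100
days, ~2 s) once for the qualitative multimedia checks, and otherwise
uses a 20 x 15-cell, 10-day fixture (4 t release, return flux off so
extinction falls inside the short horizon). Oracle suites use 1,000
random dose series and 40 random endpoint histories. The acceptance
script calibrates the fixture-derived soil field to the published
per-group statistics and reports the paired group's statistic; those
ratios are exact properties of the dose algebra and are independent of
the seed.

## Known limitations

* The fate core is a re-engineered screening model, not a port of the
  original (unpublished) multimedia code: absolute concentration fields
  are not comparable, only qualitative structure and the downstream
  algebra.
* Single uniform grid; no terrain, no nested fine grid, no wet
  deposition, no puff splitting at long range.
* The water compartment is out of scope (never assessed by the method).
* The return-flux magnitude is a calibrated screening choice; treat the
  endpoint day as scenario-specific, not as a property of benzyl
  chloride.
* Zone percentages depend on the domain chosen: enlarging the grid
  inflates the green share mechanically.
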