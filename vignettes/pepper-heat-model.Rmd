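---
title: "A process-based model of pepper growth and yield under heat stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A process-based model of pepper growth and yield under heat stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepsim)
```

## The model

`pepsim` simulates one pepper season on a daily timestep in the
radiation-use-efficiency tradition of EPIC/ALMANAC-type crop models. A
season is a sequence of daily updates of a small state vector (development
stage, leaf area index, biomass, plant nitrogen, soil water), driven by
daily weather (Tmax, Tmin, global radiation, precipitation) and a crop
parameter set.

**Phenology.** Development is clocked by degree days. The daily heat unit
is the mean of the temperature extremes above the base temperature TG,
capped at TB − TG so that days hotter than the optimum TB earn no extra
development:

$$HU_t = \min\!\big(\max(\tfrac{T_{max}+T_{min}}{2} - TG,\, 0),\; TB - TG\big)$$

The heat-unit index $HUI_t = \sum_{s\le t} HU_s / PHU$ runs from 0 at
planting to 1 at physiological maturity; the simulation stops when it
reaches 1 or the weather series ends. The cap matters for warming
scenarios: it makes the degree-day sum monotone in temperature, so a
uniformly warmed season can never mature later than its baseline — the
mechanism behind the "shorter season, less interception" yield loss.

**Canopy.** Potential leaf-area development follows the two-parameter
S-curve $f(x) = x/(x + e^{l_1 - l_2 x})$, fixed by two points packed as
decimal codes (integer part: percent of season; two fraction digits:
fraction of maximum — `10.19` means 19 % of maximum LAI at 10 % of the
season). The same functional form, on an absolute abscissa, maps stand
density to the attainable fraction of the maximum LAI (the population
factor). Daily LAI growth is the potential increment
$DMLA \cdot pop \cdot (f(HUI_t) - f(HUI_{t-1}))$ scaled by the day's
growth regulator; after the season fraction DLAI the canopy senesces
linearly in HUI to zero at maturity.

**Growth.** Intercepted photosynthetically active radiation is Beer's law
on half of global radiation, $IPAR = 0.5\,R_s(1 - e^{-k\,LAI})$, and daily
biomass gain is $\Delta B = WA \cdot IPAR \cdot REG$ with WA the potential
growth rate (kg ha⁻¹ per MJ m⁻² intercepted PAR). $REG = \min(ts, ws, ns)$
is the most-limiting of three stress factors, each in [0, 1]:

- *temperature*: $ts = \sin\big(\frac{\pi}{2}\frac{T_{avg}-TG}{TB-TG}\big)$,
  clamped, mirrored above the optimum and zero beyond TB + (TB − TG);
- *water*: the soil-water fraction of half the bucket capacity, capped at 1;
- *nitrogen*: plant N relative to the demand of a declining dilution curve
  $a + b e^{-c\,HUI}$ anchored at the calibrated fractions BN1 (emergence),
  BN2 (midseason) and BN3 (maturity) — exact at the endpoints, exact or
  least-squares at midseason depending on whether the three anchors admit
  an exponential interpolant.

**Water and nitrogen.** The soil is a single bucket. Evaporative demand is
Hargreaves-type, $PET = 0.0135\,(T_{avg}+17.8)\,R_s/2.45$ mm, split by
canopy cover into transpiration ($\min(1, LAI/3)$ of PET) and soil
evaporation ($e^{-k\,LAI}$ of PET), both throttled as the bucket empties.
An automatic irrigation event (default 25 mm) fires whenever the water
stress factor falls below the trigger. Season nitrogen supply is released
pro-rata with HUI — a deliberate simplification that mimics regular drip
fertigation rather than a soil N cycle. Plant uptake follows dilution-curve
demand against the released pool.

**Yield.** The harvest index ramps linearly from 0 at the flowering stage
(`hui_flower`, default 0.30) to the calibrated HI at maturity, so that
mid-season harvests — the 35- and 75-day greenhouse cuts — carry a
consistent, lower realized HI without modelling individual fruits. At
maturity, yield = HI × biomass exactly.

## Parameter sets

The packaged registry (`get_parameter_set()`) holds the four calibrated
sets: accessions PHR18 (heat-sensitive, fruit-prioritizing) and PHR23
(heat-tolerant, large-canopied) under greenhouse control (28/18 °C
day/night) and heat (30/22 °C) regimes. Heat sets carry lower WA (24/25 vs
33/37), longer PHU (3000 vs 1800 °C day), front-loaded canopy curves, and
shifted population points. For open-field use the control WA becomes 27
(the value calibrated against an open-field trial), the other sets are
scaled by the same 27/33 ratio — the field experiment was run with the
control genotype only, so a proportional transfer is the least-assuming
extension — and leaf decline moves from 0.99 to 0.9 of the season, because
field crops are harvested as their leaf area declines while greenhouse
harvests fall within active growth.

Two engine constants do not appear in the calibrated tables and take
standard values from this model family's literature: the light-extinction
coefficient `k_ext = 0.65` and the flowering stage `hui_flower = 0.30`.
Both are fields of the parameter set and can be overridden.

Two labelling ambiguities were resolved as follows: TB is read as the
*optimal* and TG as the *base* temperature (30/10 °C), following the
parameter table's own definitions; and the integer part of the population
codes `4.99`/`6.99`/`8.99` is read as the density in plants m⁻² (4, 6, 8),
per the printed code convention.

## Calibration procedures

- **Kjeldahl total N** (`kjeldahl_total_n`): the titration equation
  $((ml_{sample}-ml_{blank}) \cdot N_{HCl} \cdot 14.01 \cdot 100) / (1000
  \cdot mass)$, g N per kg sample; linear in net volume and normality, and
  the exact inverse of the synthetic titration generator.
- **Harvest index** (`harvest_index`): fruit over total mass, reported to
  2 decimals, the tabulation precision.
- **Leaf-area curve** (`fit_lai_curve`): observations are normalized by the
  maximum LAI, the S-curve is initialized from the exact linearization
  $\log(x(1-y)/y) = l_1 - l_2 x$ restricted to well-conditioned mid-range
  points (0.05 < y < 0.95), refined by Nelder–Mead least squares on the
  original scale, and re-encoded as two point codes: the observed season
  fraction nearest 10 %, and the fraction where the fitted curve crosses
  95 % of maximum — solved continuously but only *within* the observed
  range (no extrapolation; if the curve has not plateaued by the last
  observation, that fraction is reported). Noiseless observations generated
  from a code pair with a .95 second ordinate reproduce the codes exactly.
  The procedure presumes observations taken under near-optimal growing
  conditions, as in the fertigated calibration greenhouse; under strong
  stress the realized trajectory is flattened below the optimal curve and
  the recovered codes describe the realized, not the potential, canopy.
- **Nitrogen fractions** (`estimate_bn`): N mass fraction at the sampling
  stages nearest HUI 0.5 and 1.0, to 3 significant figures. When dry mass
  is absent from a record, (1 − moisture) × fresh mass is the denominator.
- **PHU and field WA** (`estimate_phu`, `estimate_wa_field`): grid searches
  minimizing absolute yield error, ties broken toward the smaller
  candidate. The PHU default bracket (1200–3500 by 50) spans the calibrated
  greenhouse values and the site range. The objective is yield, not
  phenology dates, matching how the sites were calibrated; a maturity-date
  objective is available behind the `objective` flag.

## Synthetic inputs

All inputs the analysis assumes can be generated in code, so every stage is
testable without external data.

- **Greenhouse weather**: day/night setpoints with optional Gaussian jitter
  (the treatment regime was 30/22 °C for 77 days; the control 28/18 °C).
  Radiation defaults to a constant 18 MJ m⁻² d⁻¹, a typical bright-season
  value, as in-house radiation records are not available. Real greenhouses
  excurse far above setpoints on ventilation-limited days; the jitter (and
  its absence by default) is a config choice, not a claim about that
  excursion distribution.
- **Field weather** (`synth_field_weather`): a seasonal sinusoid peaking in
  early August plus AR(1) daily anomalies (sd 2.5 °C, ρ 0.65), clear-sky
  radiation damped on wet days, and a monsoon-modulated occurrence/amount
  rainfall process, in three Korean-like latitude bands. This is a
  statistical emulator sufficient to exercise the engine and scenario
  machinery — not a weather-generator port, and not a reanalysis: it has no
  interannual trend, no typhoons, and temperature is uncoupled from rain.
- **Trial observations** (`gen_trial`): engine trajectories sampled at the
  trial's measurement days with per-variable Gaussian noise whose default
  sds are transcribed from the packaged trial summaries' ± values. Those
  printed dispersions do not state whether they are sd or se; they are
  interpreted as standard deviations throughout. Invariants (fruit ≤ total,
  moisture in [0, 100]) are enforced by clamping, not resampling, keeping
  seeds stable.
- **Site yields** (`gen_site_yields`): engine yields at known "true" PHU
  plus noise, enabling recovery tests of the calibration searches.

## The scenario experiment

`run_scenarios()` reproduces the structure of the multi-site warming
analysis: per site and synthetic year, a reference season with the
accession's control-condition field parameters, and one season per
temperature increment (+3/+4/+5 °C added to both daily extremes) with the
heat-condition field parameters — warmed crops are assumed to express the
heat-calibrated physiology. The site's PHU is held fixed across increments
(warming perturbs the weather, not the site's heat requirement), yields are
averaged over years (default 10, mirroring a 2014–2023 reference window),
and reported as `yield(percent)` cells.

The nine default sites span seven provinces; their PHU values (1500–1800)
are package-assigned stand-ins following the known regional gradient —
lower in the mountainous northeast, higher in the south — because per-site
calibrated values are not published. Tabulated integer percent changes use
round-half-away-from-zero, the only integer rounding consistent with the
published cells (e.g. −31.5 → −32).

## What passing tests do and do not show

The test suite verifies the reporting arithmetic against the packaged
published summaries (all eight harvest indices, the integer percent
differences, the measured/simulated ratios, and the RMSE 0.75 Mg ha⁻¹ /
|PBIAS| 1.5 % / mean simulated 8.7 Mg ha⁻¹ of the sixteen heat-unit-test
pairs), the engine's conservation and ordering properties, and calibration
recovery on synthetic data. It does *not* certify predictive skill on real
fields: the published simulated yields were produced with unpublished
in-house greenhouse records and station weather, so they serve as
plausibility bands only. On the shipped synthetic configuration the
direction of every published scenario claim holds — warming reduces yield
at every site, the larger-canopied accession loses more, maturity arrives
1–2 months earlier, irrigation demand rises — but the loss magnitudes run
deeper (≈70–85 %) than the published 31–54 %, chiefly because the
synthetic sites are warmer relative to their assigned PHU than the real
stations and because the proportionally scaled heat-set WA compounds with
the shortened season. Magnitude claims are therefore never asserted, only
orderings.

One published cell is internally inconsistent and is pinned as such in the
acceptance tests: the PHR23 Hamyang +5 °C percent change prints −48, while
its own printed yield pair (7.27 vs 13.84) gives −47.5 → −47 under
half-away rounding; the printed integer evidently came from unrounded
yields.

## Numerical choices and degenerate inputs

- Degree days use the daily mean of the two extremes; no sub-daily
  interpolation.
- The S-curve solve is an exact 2×2 linear system; coincident abscissae,
  non-increasing point pairs, and pairs implying $l_2 \le 0$ are rejected.
- The dilution-curve exponent falls back to a bounded 1-D optimization
  (c ∈ (10⁻⁶, 50]) when the three anchors admit no exact exponential.
- Grid searches skip candidates whose season fails (e.g. never maturing)
  and error only if no candidate yields a finite loss.
- A season needs at least 10 days of weather from planting; an all-dark
  season yields exactly zero; termination is at HUI ≥ 1 even if weather
  continues.
- All generators take one explicit integer seed and restore the caller's
  RNG state; scenario runs derive per-site-year seeds from the master seed,
  so reports are byte-reproducible (provenance headers omit wall-clock
  time by default for exactly this reason).

## Problem sizes

Defaults were chosen so a full analysis runs comfortably on a laptop: the
scenario experiment simulates 9 sites × 10 years × (1 + 3 increments) × 2
accessions ≈ 720 seasons of ~120–180 days each; calibration recovery
checks use 20 seeded replicates against a 47-point PHU grid and a 26-point
WA grid; the noisy curve-recovery study uses 200 seeded replicates.

## Known limitations

Beyond the weather emulator's simplifications: no disease or pest coupling
(the trials' second year suffered substantial virus damage, which the
model cannot represent), no CO₂ response, no photoperiod or vernalization,
a single soil layer, no root detail, and nitrogen that is rarely limiting
under the default fertigation supply — the shipped scenario configuration
records zero nitrogen-stress days at every site and increment, so the
published increase of nitrogen stress with warming is not informative here
(the comparison holds only as an equality). The model inherits the harvest-index
ramp rather than a drought-adjusted harvest index, whose original
configuration is not documented.
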