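---
title: "Methods: from station weather to heat stress, heat strain and heat-attributable mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from station weather to heat stress, heat strain and heat-attributable mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioheat)
```

## The problem

Prolonged Central European heat waves load the human thermoregulatory and
circulatory systems and raise all-cause mortality. Quantifying that chain
needs several layers glued together: hourly station meteorology (air
temperature `ta`, vapour pressure `vp`, 10-m wind `v10`, total cloud cover
`N`), a radiation model that turns cloud cover into the radiant load on a
person, the Universal Thermal Climate Index (UTCI) as the integrating
thermal-stress measure, a human heat-balance model for physiological
strain, climatological indicators that put a month in its multi-year
context, and finally mortality measures that attribute part of the monthly
death count to strong heat. `bioheat` implements that chain end to end and
ships a synthetic-data module so every stage can be exercised and
validated without access to national station and mortality archives.

## Radiation chain

UTCI needs the mean radiant temperature `Tmrt`, which station archives do
not record. We reconstruct it from what they do record:

* **Solar position** uses the standard low-precision astronomical
  algorithm (Fourier-series declination and equation of time, then the
  hour-angle formula). Accuracy is a few tenths of a degree; the test
  suite pins it against closed-form solstice/equinox geometry to 0.5°.
* **Clear-sky irradiance** is the one-parameter transmittance model
  `S0 · tau^(1/sin h) · sin h` with `S0 = 1361` W·m⁻² and a broadband
  transmittance `tau = 0.75` per unit relative air mass — the simplest
  model that needs no aerosol input, which the station tables cannot
  supply.
* **Cloud attenuation** is the Kasten–Czeplak factor
  `1 − 0.75·N^3.4`, chosen because it requires total cloud cover only
  (no direct/diffuse split is attempted).
* **Tmrt** combines absorbed short-wave on a standing person (projected
  area factor `0.308·cos(h(0.998 − h²/50000))`, albedo 0.3) with sky and
  ground long-wave exchange. Sky emissivity is the Brunt form
  `0.605 + 0.048·√vp` with the Crawford–Duchon cloud interpolation
  `eps = N + (1 − N)·eps_clear`; the ground radiates as a black body at
  air temperature. The interpolation form is deliberate: it makes an
  overcast sky a black body, so at night under full cloud the person sits
  in an isothermal enclosure and `Tmrt = ta` exactly — a limit the tests
  assert. All constants live in `radiation_constants()` and are echoed
  into every run's metadata.

This chain will not reproduce any particular proprietary radiation
implementation bit for bit; validation therefore targets physical
properties (monotonicity in irradiance, temperature and cloud; the
enclosure limit) and category-level agreement, not map-level equality.

## UTCI

`compute_utci()` evaluates the operational sixth-order polynomial
approximation of UTCI in `ta`, `va` (10-m wind), `Tmrt − ta` and vapour
pressure. The 210 published coefficients ship as a versioned CSV with a
checksum guard; the test suite re-evaluates the polynomial through an
independently coded explicit expression and requires agreement within
0.05 °C on 1000 random in-domain points, plus the equivalent-temperature
identity `|UTCI − ta| ≤ 1 °C` at reference conditions (calm 0.5 m·s⁻¹
wind, `Tmrt = ta`, 50 % relative humidity capped at 20 hPa) for
`ta ∈ [15, 35]`.

Inputs outside the approximation's validity domain (`ta ∈ [−50, 50]` °C,
`va ∈ [0.5, 17]` m·s⁻¹, `Tmrt − ta ∈ [−30, 70]` °C, `vp ≤ 50` hPa) are
clipped to the nearest edge and flagged rather than rejected: calm winds
below 0.5 m·s⁻¹ are routine in station data and an error would discard
exactly the still, hot hours that matter most.

Stress categories follow the UTCI assessment scale with bands half-open
on the left and closed on the right, matching the printed one-decimal
edges (26.0 °C is still "no thermal stress", 26.1 °C is moderate heat
stress). The cold half of the scale is collapsed into a single
`below_scale` class because a June heat analysis never uses it.

Whether a day's category should come from the midday (12 UTC) UTCI or
from the daily maximum is genuinely open; midday observations represent
the most heat-stressed part of the day in Central Europe (14:00 local
summer time), so `utci_12` is the default `category_basis`, with
`utci_max` selectable in the run config.

## Heat strain

The heat balance `S = M + Q + E + C + Res` is evaluated per station-hour
for a reference person walking 4 km·h⁻¹ (`M = 135` W·m⁻², configurable):

* `Q` — long-wave exchange between skin and the solar-inclusive `Tmrt`
  (`eps_p = 0.97`); because `Tmrt` already contains the absorbed solar
  load, `Q` is positive in sunshine and mildly negative at night.
* `C` — convective exchange `hc·(ta − Tsk)` with `hc = 8.3·v₁.₂^0.6`;
  wind is converted from 10 m to 1.2 m by a neutral logarithmic profile
  over roughness 0.01 m (factor ≈ 0.69).
* `Res` — respiratory loss `−[0.0014·M·(34 − ta) + 1.72·10⁻⁵·M·(5867 −
  100·vp)]`, clipped to be a loss.
* `Tsk` — mean skin temperature from the empirical linear response
  `26.0 + 0.21·ta + 0.02·Tmrt + 0.01·M` (°C); a documented substitute for
  undisclosed physiological-model internals, chosen to give ~31 °C in
  mild conditions and ~35 °C in severe heat.
* `E` — sweat evaporation. The demand is `Ereq = M + Q + C + Res`; the
  ceiling is `Emax = k·v₁.₂·0.6·(56 − vp)` with `k = 7.0` clothed /
  `11.7` naked. Sweating efficiency falls as the skin wets: with
  wettedness `w = Ereq/Emax`, the realised evaporation is
  `Ereq·(1 − w/2)`, never more than `Emax`. Hence
  `S = Ereq²/(2·Emax)` in the sweating regime — storage accumulates
  smoothly as demand approaches capacity, rather than jumping from zero
  only once `Ereq > Emax`. Without this efficiency term the
  overheating-hours indicator would be degenerate (zero at any normal
  wind speed); with it, hot clear days show several midday hours above
  the `S > 15` W·m⁻² overheating threshold, matching how the indicator
  behaves in practice.

The identity `S = M + Q + E + C + Res` holds to machine precision for
every computed hour and is asserted as such. Heart rate is the
Fuller–Brouha regression `HR = 22.4 + 0.18·M + 0.25·(5·ta + 2.66·vp)`
(warning level 90 beats·min⁻¹); sultriness is
`HSI = 100·Ereq/Emax`, floored at 0 (no sweating demand) and capped at
100 (saturated or overwhelmed air), with `HSI > 30 %` marking intensive
sultriness. Daily budgets count hours above/below the strict thresholds:
heat stress time (UTCI > 26 °C), heat recovery time (UTCI < 18 °C) —
their complement is exactly the 18–26 °C comfort band — and hours with
`S > 15`, `HR > 90`, `HSI > 30`. A static annotation (not a simulation)
flags days where `S > 15` persists for 3 h or more, the regime associated
with a ~2 °C core-temperature rise.

## Climatology and mortality

Heat indicators use strict thresholds throughout: hot / very hot /
extremely hot days (`tmax > 25 / 30 / 35` °C), warm / tropical nights
(`tmin > 18 / 20` °C), and heat waves as maximal runs of at least 3
consecutive days with `tmax > 30` °C — two runs separated by a single
cooler day are two waves. Anomalies are reported both in native units and
in multiples of the reference-period standard deviation; the sample
(n − 1) SD is used, a documented choice since the convention is often
left unstated in climatological reporting.

Mortality has two published measures and one validation estimator:

* `TMrel = 100·TMx/TMavg` — the month's deaths as a percent of the
  reference-period mean; reference years' TMrel values average to exactly
  100 against their own mean.
* `SHRM = 2.595·PopRate·(SHS + VSHS)` — model-attributed deaths from
  strong heat, linear in city population per 100,000 and in the count of
  strong/very-strong heat-stress days. The 2.595 coefficient is adopted
  verbatim from the published model; its time basis is not derivable, so
  outputs are labelled "model-attributed deaths per month".
  `SHRMrel` expresses it against the reference-period mean.
* `estimate_heat_effect()` — a ratio-of-means relative risk (mean deaths
  on SHS/VSHS days over mean deaths on other days) with a stratified
  percentile bootstrap. It exists to close the validation loop: inject a
  known relative risk through the synthetic generator, recover it, and
  check calibration (the null-coverage and recovery runs below).

Missing yearly mortality values are excluded from reference means, never
imputed.

## The synthetic-data module

`weather_scenario()` builds hourly air temperature as
`base + diurnal + AR(1) + wave`: a sinusoidal diurnal cycle with minimum
at 04 and maximum at 14 local solar time (asymmetric 10-h rise / 14-h
fall, centred so the daily mean equals `base_mean_ta` exactly), a
day-level AR(1) anomaly shared by all hours of a day (the simplest
process giving day-to-day weather persistence without distorting the
diurnal shape), and heat-wave windows that add a constant offset to all
hours of the affected days. Vapour pressure is lognormal capped below
saturation at the hour's temperature (no physically impossible humidity);
wind is lognormal; cloud is a Beta draw. Each variable has its own
deterministic sub-stream of the scenario seed, so adding a variable never
perturbs another's draws.

Default scenarios were calibrated once, from the published June regime,
and then frozen:

* analysis year: `base_mean_ta = 21` °C with waves on days 10–16 and
  25–27 at +7 °C — monthly mean air temperature ≈ 23 °C, two detectable
  heat waves, and ≈ 6.8 strong-heat-stress days on average (published
  event: 6.7);
* reference years: `base_mean_ta = 15` °C with two 2-day hot spells at
  +11 °C — ≈ 1.0 strong-heat day per June on average (published
  reference mean: 1.1). The resulting midday UTCI mean (~21.5 °C) runs
  about 1.5 °C warmer than the published 20.0 °C; our radiation chain is
  not the one behind the published values, and category-level rates were
  prioritised over degree-level equality because every mortality measure
  consumes category counts, not degrees.

What the generator does **not** emulate: spatial correlation between
stations, synoptic-scale persistence beyond AR(1), humidity–temperature
anticorrelation during advective heat, and urban heat-island night
effects. Passing tests therefore demonstrate the correctness of the
computational chain and the recoverability of injected effects — not that
the synthetic weather is climatologically indistinguishable from station
records.

Mortality is Poisson: `deaths ~ Poisson(baseline · RR^[strong-heat day])`
with defaults of 30 deaths/day (a city of ~800,000) and `RR = 1.5`, the
condition used by the recovery studies.

## Numerical and degenerate-input choices

* Timestamps are stored in UTC; "midday" means 12 UTC (14:00 Central
  European summer time). Local-time inputs must declare an offset.
* Cloud cover is accepted in oktas or fractions; the dialect is declared,
  never guessed; 9 oktas (sky obscured) is rejected as invalid rather
  than guessed at.
* A station-day needs ≥ 18 of 24 valid hours to count as complete
  (configurable); incomplete days are excluded from indicator counts and
  reported. A missing midday record leaves the `_12` fields `NA`.
* Division guards: zero reference SD leaves the SD-scaled anomaly
  undefined while the absolute anomaly is returned; zero reference SHRM
  leaves SHRMrel undefined; `Emax ≤ 0` (saturated air) caps HSI at 100
  and suppresses evaporation entirely.
* The bootstrap in `estimate_heat_effect()` resamples within strata so no
  resample can lose a stratum; non-finite resample ratios (all-zero
  "other" stratum draws at tiny counts) are dropped before the
  percentile.
* All seeds derived from a master seed stay below 2³¹; generator calls
  save and restore the global RNG state, so package randomness never
  perturbs a user's session stream.

## Problem sizes

The test suite and the acceptance script run on deliberately small
problems: 30-day single-station months (720 hours), 9 reference years
plus one analysis year per pipeline run, 1000-point oracle comparisons,
1000 random series for the counting brute-force checks, and 500/200
replicates for the effect-recovery and null-coverage studies. These sizes
give stable statistics (Monte-Carlo standard errors an order of magnitude
below the asserted tolerances) while keeping a full run in the tens of
seconds.

## Known limitations

* The radiation/Tmrt chain is a documented simple model; degree-level
  UTCI values will differ from implementations with other radiation
  schemes, even though category-level behaviour is robust.
* Skin temperature is an empirical linear stand-in; it is not a
  physiological simulation and the `S` diagnostics inherit that.
* SHRM is a linear attribution model with an adopted coefficient, not a
  fitted epidemiological model; it should be read as a standardised
  index, not a causal death count.
* The pipeline treats one station per city and one city per run; no
  spatial pooling, age stratification or harvesting-effect time-series
  modelling is attempted.
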