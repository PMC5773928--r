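---
title: "Predicting Medfly quarantine lengths: degree-day accumulation versus agent-based elimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting Medfly quarantine lengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medpql)
```

## The problem

When Mediterranean fruit fly (*Ceratitis capitata*) detections trigger an
eradication response, quarantine must continue past the last fly found,
because non-detection does not prove elimination. The regulatory practice is
to wait until three generations could have elapsed under a thermal-unit
("degree-day") development model: using the California standard, a base
development temperature of 12.39 °C and 345.56 Celsius degree-days per
generation, so quarantine ends when 3 × 345.56 = 1036.68 DDc have
accumulated since the last detection. We call the number of days this takes
from a given start date the degree-day predicted quarantine length (DD PQL).

A complementary approach simulates the outbreak population itself: a
stochastic, non-spatial, stage-structured agent model in which individual
flies develop with temperature, die from baseline, control-induced, and
acute-temperature mortality, and reproduce subject to sterile insect
technique (SIT) pressure. Elimination is explicit — the simulation runs
until the last agent dies. Because most biological parameters are only known
to within ranges, each start date is swept with a Latin hypercube sample
(LHS) of parameter space; the day by which 95% of the ensemble has reached
elimination is the agent-based predicted quarantine length (ABS PQL).

This package implements both calculators over hourly temperature series, the
cleaning pipeline that prepares such series, a synthetic climate generator
used for testing and demonstration, and the "normals" statistics (per
calendar day, across years) used to compare the two predictions.

## Temperature data model

All computation consumes a gap-free, hourly-aligned temperature series in
which every hour carries a provenance flag: `observed`,
`interpolated_small_gap` (linear interpolation in time across gaps of at
most 3 hours), or `interpolated_day_over_day` (larger gaps are filled per
hour-of-day by interpolating between the nearest earlier and later days that
have a value at the same hour). Timestamps are treated as local standard
time with no daylight-saving transitions; the calendar day is the
aggregation unit everywhere. Cleaning choices that the data sources leave
open:

* **Outliers.** Records deviating more than 15 °C from the rolling median of
  neighbours within ±24 h are removed. The rule is robust and
  parameter-light: isolated sensor spikes move far from the local median,
  while genuine heat waves and cold snaps move the median with them.
* **Duplicate timestamps** resolve to the mean (order-independent and
  unbiased); exact duplicates collapse.
* **Boundary gaps** (a large gap with no bracketing day on one side) are an
  error rather than an extrapolation; problem periods should be trimmed.
* **Partial first/last days** are excluded from daily extremes to avoid
  biased minima/maxima.

## Degree-day calculation

Daily degree-days above the base `b` use the single-sine method: the day's
temperature is modelled as a sinusoid between `tmin` and `tmax` with mean
`m` and half-amplitude `a`, and the area above `b` has the closed form

* 0 when `tmax <= b`,
* `m − b` when `tmin >= b`,
* `[(m − b)(π/2 − θ) + a cos θ] / π` otherwise, with `θ = asin((b − m)/a)`.

Hourly simple summation (`Σ max(T_h − b, 0)/24`) is provided for comparison;
on a truly sinusoidal day the two agree to within hourly discretisation.
Design points worth noting:

* **No upper developmental cutoff** by default, because the regulatory
  standard specifies only a base temperature; a horizontal upper-cutoff hook
  exists (`upper_cutoff`) but is off.
* **Whole-day PQL granularity**: the PQL is the smallest whole number of
  days whose cumulative degree-days reach the threshold, counting the start
  date as day 1. No within-day fractional interpolation, matching
  day-resolution reporting.
* **Censoring**: a start date whose accumulation is incomplete when the data
  end yields a censored record carrying the partial accumulation, never an
  extrapolated value.

## The elimination simulator

Agents occupy stages {egg, larva, pupa, immature adult, mature adult} with a
per-stage thermal requirement `DD_s` above a per-stage base `b_s`. Each
simulated day applies, in fixed order: (1) hourly degree-day development
with stage advancement, surplus degree-days carrying into the next stage and
sex assigned by a fair coin at adult emergence; (2) hourly acute mortality
below `cold_lethal_c` / above `heat_lethal_c` (because development completes
before any acute death within the day, the per-hour Bernoulli deaths
combine exactly into one survival draw per agent); (3) daily baseline
mortality `μ_s` combined with control mortality as independent hazards,
`p = 1 − (1 − μ_s)(1 − control)`; (4) mating — each unmated mature female is
sterilised with probability `p_sit` per day, otherwise mates fertilely if a
living mature male exists; females mate once for life; (5) oviposition —
each fertile female lays Poisson(`fecundity × dev_scale(T̄)`) eggs, where
`dev_scale(T̄) = max(T̄ − b_egg, 0)/(25 − b_egg)` and `T̄` is the day's mean
temperature. The event order is documented because reordering changes
trajectories. The inner loop is compiled (C++) with per-day, per-stage
prefix sums of hourly development increments, which is exactly equivalent to
hour-by-hour accumulation but O(1) per agent on non-advancement days.

A *run* is `n_sims` simulations for one start date, one per LHS-sampled
parameter vector; its ABS PQL is the smallest day by which
`ceil(0.95 n_sims)` simulations are eliminated, censored when the data or
horizon end first. A *runset* starts a run every 7 days and linearly
upsamples the PQL knots to daily values, never bridging across a censored
knot. Seeds: one master seed yields pre-drawn per-run and per-simulation
seeds, so results do not depend on execution order.

Two guards matter in practice. A simulation whose population exceeds
`max_population` (default 100,000) is censored: such a parameter vector is
not being eradicated, and simulating unbounded growth is pointless. And
`max_days` (default 730) censors simulations that outlast the horizon; both
kinds of censoring flow into the 95% rule, which tolerates up to 5%
non-eliminating simulations per run.

### Parameter ranges

The outbreak and intervention ranges are taken from the published study
design: 33–100 initial adult females (with an equal number of males, all
mature and unmated — a "standard outbreak"), SIT-induced loss of
reproduction at 0.5–1 per day, and control-induced mortality at 0.05–0.15
per day applied to all stages. The stage-level ranges are **calibrated
placeholders** (the source study's stage table is not published in the paper
body): the per-stage thermal requirements (egg 21–31, larva 84–126, pupa
128–192, immature adult 44–65.12 DDc) have midpoints summing to 345.56 DDc
above bases centred on 12.39 °C, which keeps the simulator commensurable
with the regulatory degree-day model by construction. Baseline mortalities
follow Medfly life-table magnitudes: high field mortality for eggs and
larvae (0.05–0.15/day), lower for the protected pupal stage (0.02–0.08),
and adult rates (0.02–0.08/day) consistent with multi-week adult longevity;
fecundity spans 10–30 eggs/female/day at the 25 °C reference. Acute cold is
parameterised so that only snap-level excursions are lethal
(`cold_lethal_c` in [−6, −2] °C, hourly kill probability 0.05–0.5):
literature cold-tolerance for Medfly puts hours-scale acute mortality near
and below freezing, while ordinary winter nights a few degrees above zero
are survivable. All ranges live in `bio_param_ranges()` and the pipeline
configuration; none are hard-coded in the simulator.

## The synthetic climate generator

`generate_synthetic_weather()` emulates the structure of long airport
temperature records: an annual sinusoid (default mean 17 °C, half-amplitude
9 °C, warmest day 200 — a mid-latitude, inland-California-like site), a
diurnal sinusoid (half-amplitude 6 °C peaking at 15:00), stationary AR(1)
noise (σ = 2.5 °C, hourly correlation 0.95, capturing multi-day synoptic
persistence), and Poisson-count cold snaps (3/year, 6 h, 10 °C below the
seasonal curve) matching the rare, brief events that matter to the
simulator. Optional defect injection (sensor spikes of 25–40 °C, multi-hour
observation gaps) exercises the cleaning stage, and every injection is
logged so tests can verify cleaning exactly. The generator does **not**
emulate heteroskedastic seasonal noise, weather fronts with skewed
temperature drops, multi-year climate trends, or humidity-coupled effects;
passing tests on synthetic climate therefore demonstrate correctness of the
calculators, not meteorological fidelity of any real site.

## What the two predictions do and do not share

On the default 20-year synthetic climate the package reproduces the
qualitative structure reported for real sites: degree-day PQLs are longest
for late-summer/autumn starts (accumulation stalls through winter) and
shortest for late-spring starts; agent-based PQLs follow the same seasonal
phase but with a markedly smaller swing, because mortality continues when
development stalls. A lethal cold snap shortens agent-based predictions
while leaving degree-day predictions unchanged or longer — the structural
asymmetry between an elimination model and an accumulation model.

One reported pattern is **not** reproduced, deliberately: the latitude
gradient of agent-based medians. In this implementation daily baseline
mortality is temperature-independent (the model contract), so cold-site
populations die on the same clock as warm-site ones while never reproducing
in winter (oviposition scales to zero below the egg base); colder synthetic
sites therefore get *shorter* agent-based quarantines, not longer ones. A
latitude trend like the published one requires temperature-dependent
mortality (slower senescence in cool weather), which this model does not
include. The degree-day latitude gradient is reproduced. Users comparing
sites with the agent model should keep this limitation in mind.

## Numerical and statistical choices

* Normals are computed per (month, day) key with **no running-mean
  smoothing**; Feb-29 is its own key with a smaller sample count. The
  spread statistic is the population (divisor *n*) standard deviation by
  default — consistent with min/max being population summaries — with a
  sample-σ option. Quartiles use the linear-interpolation convention.
* `normal_r2()` reports the percentage of variance captured by the mean of
  the normal, `1 − SS_res/SS_tot` against the day-of-year means; it is
  exactly 100% for any pure function of calendar day and always within
  [0, 100] when the normals come from the same series.
* The variance-ratio test on deviations from each method's own normal mean
  is two-sided by default (equivalent to mirroring the larger variance into
  the numerator), with one-sided alternatives available since the direction
  is often stated a priori.
* Nearest-station matching minimises the haversine distance, with
  deterministic tie-breaks (lower latitude, then callsign).
* Identical paired lists are defined to give t = 0, p = 1 (the textbook
  statistic is 0/0 there).
* Stochastic monotonicity in the control-mortality parameter is tested in
  distribution (means and upper quantiles across replicates), not pathwise:
  with a single shared RNG stream, one earlier death shifts all later
  draws, so pathwise coupling under common random numbers is not
  guaranteed by construction.

## Problem sizes used by the test-suite and acceptance script

The shipped checks run at desk scale, chosen to exercise every code path
while staying fast: 20 synthetic years with 100 simulations per run at
14-day run spacing for the seasonal-structure comparison (the study design
they scale down used 2500 simulations per run at 7-day spacing over 43–66
years per site — about 86 million simulations); 1,000 random days against
10,000-point numerical integration for the single-sine oracle; 200–300
replicates for the simulator-versus-cohort-model cross-checks. The 2500/7
full-fidelity settings remain available through the configuration file.

## Known limitations

* Non-spatial, single-population model; no explicit sterile-male cohort
  dynamics, genetics, or density dependence.
* Temperature-independent baseline mortality (see above).
* The oviposition rate scales linearly with mean temperature above the egg
  base and is uncapped above the 25 °C reference.
* The simplified hourly CSV dialect replaces the fixed-width NOAA ISD
  format; quality codes, humidity and wind are out of scope.
* Surplus degree-days crossing a stage boundary carry into the next stage
  in DDc units even though the stages' base temperatures may differ
  slightly; with the default bases (all centred on 12.39 °C) the effect is
  negligible.
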