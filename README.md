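# medpql

Predicted quarantine lengths for Mediterranean fruit fly (*Ceratitis
capitata*, "Medfly") outbreaks, by two routes:

* **DD PQL** — the regulatory degree-day calculation: the number of days,
  from the last fly detection, for three generations' worth of thermal
  development to accumulate. Degree-days above the base `b = 12.39` °C are
  computed daily by the single-sine method (with hourly simple summation as
  a comparator), and quarantine ends when `3 × 345.56 = 1036.68` DDc have
  accumulated (the California Department of Food and Agriculture standard).
* **ABS PQL** — an explicit elimination model: a stochastic, non-spatial,
  stage-structured agent simulation of the outbreak population under
  sterile-insect-technique pressure and control mortality, swept over
  biological parameter uncertainty with Latin hypercube sampling; the PQL is
  the day by which 95% of the ensemble has reached elimination.

Both are driven by hourly temperature series. The package also provides the
cleaning pipeline for such series (outlier removal, hourly resampling,
small-gap and day-over-day gap filling, with per-hour provenance flags), a
synthetic hourly climate generator (seasonal + diurnal sinusoids, AR(1)
weather noise, rare brief cold snaps, optional data defects), day-of-year
"normals" statistics without smoothing, and site-level comparison tools
(variance decomposition, latitude regression, nearest-station matching,
paired method comparison). It is aimed at quantitative biosecurity analysts
who want reproducible quarantine-length estimates and their uncertainty,
rather than single projections from average temperatures.

For whom the two models disagree and why — and what that means for ending
quarantines early or extending them — see the methods vignette
(`vignettes/predicted-quarantine-length.Rmd`).

## Worked example

Three years of synthetic mid-latitude hourly weather, degree-day PQLs every
30 days, and a small agent-based runset every 60 days:

```r
library(medpql)

climate <- synthetic_climate_params(seed = 7)   # inland-California-like defaults
weather <- generate_synthetic_weather(climate, n_years = 3)

model <- degree_day_model()                     # base 12.39 degC, 3 x 345.56 DDc
head(dd_pql_series(weather$clean, model, every_days = 30), 4)
#> # A tibble: 4 × 5
#>   start_date method      pql_days censored accum_dd
#>   <date>     <chr>          <int> <lgl>       <dbl>
#> 1 2000-01-01 single_sine      193 FALSE       1046.
#> 2 2000-01-31 single_sine      164 FALSE       1039.
#> 3 2000-03-01 single_sine      136 FALSE       1045.
#> 4 2000-03-31 single_sine      111 FALSE       1046.

rs <- run_runset(weather$clean, every_days = 60, n_sims = 50, seed = 42,
                 max_days = 500)
head(rs$runs, 4)
#> # A tibble: 4 × 5
#>   start_date method pql_days censored n_sims
#>   <date>     <chr>     <int> <lgl>     <dbl>
#> 1 2000-01-01 abs          64 FALSE        50
#> 2 2000-03-01 abs          73 FALSE        50
#> 3 2000-04-30 abs         249 FALSE        50
#> 4 2000-06-29 abs         138 FALSE        50
```

Reading the output: a quarantine starting on 1 January needs 193 days for
three degree-day generations (accumulation crawls through winter), while one
starting on 31 March needs only 111. The agent-based predictions follow the
same seasonal phase but swing differently: the 1 January ensemble is 95%
eliminated after 64 days (mortality continues while development stalls, and
winter oviposition is nil), whereas the 30 April ensemble takes 249 days
(spring eggs mature and must die out). `pql_days` is censored (empty) when
the temperature record or simulation horizon ends first.

The full pipeline — weather, both PQL series, normals, comparison report,
manifest — runs from a YAML config:

```r
run_pipeline(validate_config("config.yaml"))
```

A thin command-line wrapper with the same stages is in
`inst/scripts/medpql.R` (`synth-weather | clean-weather | dd-pql | abs-pql |
normals | all`).

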