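# Shared fixture builders (all data generated in code).

# constant-temperature hourly series of n_days starting 2010-01-01
constant_series <- function(temp = 20, n_days = 3) {
  ts <- seq(as.POSIXct("2010-01-01 00:00:00", tz = "UTC"),
            by = 3600, length.out = n_days * 24)
  tibble::tibble(timestamp = ts, temp_c = rep(temp, length(ts)),
                 fill_flag = "observed")
}

# one parameter vector at its range midpoint, with overrides
fixed_bio_params <- function(...) {
  r <- bio_param_ranges()
  p <- setNames((r$low + r$high) / 2, r$param)
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- unlist(over)
  p
}

# quick synthetic climate for tests: quiet by default
quiet_climate <- function(seed = 1, ...) {
  synthetic_climate_params(noise_sigma = 0, coldsnap_rate = 0,
                           defect_outlier_rate = 0, defect_gap_rate = 0,
                           seed = seed, ...)
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# write a small demo pipeline config
demo_config <- function(path, out_dir, seed = 5, n_years = 3, n_sims = 20,
                        every_days = 60, two_sites = FALSE) {
  south <- "
  - callsign: SYNS
    name: synthetic warm southern site
    latitude: 26.0
    longitude: -80.3
    weather:
      synthetic:
        n_years: %d
        annual_mean: 24
        annual_amplitude: 4
"
  lines <- sprintf("
seed: %d
output_dir: %s
popsim:
  n_sims: %d
  every_days: %d
  max_days: 400
sites:
  - callsign: SYNN
    name: synthetic cool northern site
    latitude: 37.6
    longitude: -122.4
    weather:
      synthetic:
        n_years: %d
        annual_mean: 15
        annual_amplitude: 7
%s", seed, out_dir, n_sims, every_days, n_years,
    if (two_sites) sprintf(south, n_years) else "")
  writeLines(lines, path)
  path
}
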