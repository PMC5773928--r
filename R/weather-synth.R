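#' Parameters for the synthetic hourly climate generator
#'
#' Defaults describe a mid-latitude, inland-California-like site: a warm dry
#' summer, cool winter with occasional brief cold snaps, a pronounced diurnal
#' cycle, and autocorrelated synoptic-scale noise. Temperatures are built as
#' annual sinusoid + diurnal sinusoid + AR(1) noise, minus cold-snap
#' excursions; optional data defects (spikes and gaps) exercise the cleaning
#' stage.
#'
#' @param annual_mean Annual mean temperature, degC.
#' @param annual_amplitude Half the seasonal swing of the daily mean, degC.
#' @param annual_phase Day-of-year of the warmest day.
#' @param diurnal_amplitude Half the mean daily temperature range, degC.
#' @param diurnal_phase Hour of the daily maximum (0-23).
#' @param noise_sigma Stationary standard deviation of the AR(1) noise, degC.
#' @param noise_rho Hour-to-hour AR(1) correlation, in `[0, 1)`.
#' @param coldsnap_rate Expected cold snaps per year (Poisson count per year).
#' @param coldsnap_duration Duration of each snap, hours.
#' @param coldsnap_depth Depth of each snap below the seasonal curve, degC.
#' @param defect_outlier_rate Expected injected sensor spikes per year.
#' @param defect_gap_rate Expected injected observation gaps per year.
#' @param defect_gap_hours Length of each injected gap, hours.
#' @param seed Integer seed; generation is reproducible for a given seed.
#' @return A list of class `synthetic_climate_params`.
#' @export
synthetic_climate_params <- function(annual_mean = 17, annual_amplitude = 9,
                                     annual_phase = 200, diurnal_amplitude = 6,
                                     diurnal_phase = 15, noise_sigma = 2.5,
                                     noise_rho = 0.95, coldsnap_rate = 3,
                                     coldsnap_duration = 6, coldsnap_depth = 10,
                                     defect_outlier_rate = 0, defect_gap_rate = 0,
                                     defect_gap_hours = 12, seed = 1L) {
  stopifnot(annual_amplitude >= 0, diurnal_amplitude >= 0, noise_sigma >= 0,
            noise_rho >= 0, noise_rho < 1, coldsnap_rate >= 0,
            defect_outlier_rate >= 0, defect_gap_rate >= 0)
  structure(list(
    annual_mean = annual_mean, annual_amplitude = annual_amplitude,
    annual_phase = annual_phase, diurnal_amplitude = diurnal_amplitude,
    diurnal_phase = diurnal_phase, noise_sigma = noise_sigma,
    noise_rho = noise_rho, coldsnap_rate = coldsnap_rate,
    coldsnap_duration = coldsnap_duration, coldsnap_depth = coldsnap_depth,
    defect_outlier_rate = defect_outlier_rate, defect_gap_rate = defect_gap_rate,
    defect_gap_hours = defect_gap_hours, seed = as.integer(seed)
  ), class = "synthetic_climate_params")
}

#' Deterministic seasonal + diurnal baseline of the generator
#'
#' The noise-free expected temperature at given timestamps under the
#' generator's sinusoidal model; used both internally and as the closed-form
#' reference curve in calibration checks.
#'
#' @param timestamps POSIXct vector.
#' @param params A [synthetic_climate_params()] object.
#' @return Numeric vector of degC values.
#' @export
synthetic_baseline <- function(timestamps, params) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  doy <- lt$yday + 1 + lt$hour / 24
  hour <- lt$hour
  params$annual_mean +
    params$annual_amplitude * cos(2 * pi * (doy - params$annual_phase) / 365.25) +
    params$diurnal_amplitude * cos(2 * pi * (hour - params$diurnal_phase) / 24)
}

#' Generate a synthetic hourly temperature series
#'
#' Builds `n_years` calendar years of hourly temperatures starting at
#' `start_year`-01-01 00:00: sinusoidal annual and diurnal cycles plus AR(1)
#' noise, with Poisson-count cold snaps each year (each subtracting
#' `coldsnap_depth` degC for `coldsnap_duration` hours). If defect rates are
#' positive, sensor spikes are added and observation gaps removed from a
#' corrupted copy so that the cleaning stage can be exercised; every
#' injection is recorded in the log.
#'
#' @param params A [synthetic_climate_params()] object.
#' @param n_years Number of calendar years (>= 1).
#' @param start_year First calendar year of the series.
#' @param site Optional site metadata to attach.
#' @return A list of class `synthetic_weather` with elements
#'   `clean` (gap-free `hourly_temps` ground truth),
#'   `raw` (tibble with defects applied; equals `clean`'s columns when defect
#'   rates are zero), `log` (injection log tibble with `type`, `timestamp`,
#'   `n_hours`, `true_value`, `injected_value`), and `params`.
#' @export
generate_synthetic_weather <- function(params, n_years, start_year = 2000L,
                                       site = NULL) {
  stopifnot(inherits(params, "synthetic_climate_params"), n_years >= 1)
  set.seed(params$seed)

  start <- as.POSIXct(sprintf("%d-01-01 00:00:00", start_year), tz = "UTC")
  end <- as.POSIXct(sprintf("%d-12-31 23:00:00", start_year + n_years - 1L), tz = "UTC")
  ts <- seq(start, end, by = 3600)
  n <- length(ts)

  temp <- synthetic_baseline(ts, params)
  if (params$noise_sigma > 0) {
    innov_sd <- params$noise_sigma * sqrt(1 - params$noise_rho^2)
    e <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), params$noise_rho,
                                  method = "recursive",
                                  init = rnorm(1, 0, params$noise_sigma)))
    temp <- temp + e
  }

  log <- tibble::tibble(type = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                        n_hours = integer(), true_value = numeric(),
                        injected_value = numeric())

  years <- unique(as.POSIXlt(ts, tz = "UTC")$year)
  year_of <- as.POSIXlt(ts, tz = "UTC")$year
  if (params$coldsnap_rate > 0 && params$coldsnap_duration > 0) {
    for (y in years) {
      k <- rpois(1, params$coldsnap_rate)
      if (k == 0) next
      yr_idx <- which(year_of == y)
      starts <- sort(sample(yr_idx, k))
      for (s in starts) {
        win <- s:min(s + params$coldsnap_duration - 1L, n)
        temp[win] <- temp[win] - params$coldsnap_depth
        log <- dplyr::bind_rows(log, tibble::tibble(
          type = "coldsnap", timestamp = ts[s], n_hours = length(win),
          true_value = NA_real_, injected_value = -params$coldsnap_depth))
      }
    }
  }

  clean <- new_hourly_temps(ts, temp, rep("observed", n), site = site)

  raw <- tibble::tibble(timestamp = ts, temp_c = temp)
  if (params$defect_outlier_rate > 0) {
    k <- rpois(1, params$defect_outlier_rate * n_years)
    if (k > 0) {
      at <- sort(sample.int(n, k))
      mag <- sample(c(-1, 1), k, replace = TRUE) * runif(k, 25, 40)
      log <- dplyr::bind_rows(log, tibble::tibble(
        type = "outlier", timestamp = ts[at], n_hours = 1L,
        true_value = raw$temp_c[at], injected_value = raw$temp_c[at] + mag))
      raw$temp_c[at] <- raw$temp_c[at] + mag
    }
  }
  if (params$defect_gap_rate > 0) {
    k <- rpois(1, params$defect_gap_rate * n_years)
    if (k > 0) {
      # keep gaps off the series boundary so they remain fillable
      margin <- 48L + params$defect_gap_hours
      at <- sort(sample(seq(margin, n - margin), k))
      drop <- integer()
      for (s in at) {
        win <- s:(s + params$defect_gap_hours - 1L)
        drop <- c(drop, win)
        log <- dplyr::bind_rows(log, tibble::tibble(
          type = "gap", timestamp = ts[s], n_hours = params$defect_gap_hours,
          true_value = NA_real_, injected_value = NA_real_))
      }
      raw <- raw[-unique(drop), , drop = FALSE]
    }
  }

  structure(list(clean = clean, raw = raw, log = log, params = params),
            class = "synthetic_weather")
}

#' Impose a cold snap on an hourly series
#'
#' Clamps temperatures in the window to at most `floor_c`; hours outside the
#' window are unchanged. Used to probe the asymmetry between mortality-aware
#' and accumulation-only quarantine predictions: brief lethal cold kills
#' simulated flies but only slows degree-day accumulation.
#'
#' @param series An `hourly_temps` tibble.
#' @param start POSIXct start of the snap (must lie within the series).
#' @param duration_h Snap duration in hours.
#' @param floor_c Ceiling imposed on temperatures in the window, degC.
#' @return The modified series.
#' @export
inject_cold_snap <- function(series, start, duration_h, floor_c) {
  t_num <- as.numeric(series$timestamp)
  s <- as.numeric(start)
  i0 <- match(s, t_num)
  if (is.na(i0) || i0 + duration_h - 1L > nrow(series)) {
    stop("cold-snap window outside the series range")
  }
  win <- i0:(i0 + duration_h - 1L)
  series$temp_c[win] <- pmin(series$temp_c[win], floor_c)
  series
}
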