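#' Regulatory degree-day model settings
#'
#' Defaults follow the California Department of Food and Agriculture
#' quarantine standard for Medfly: a base development temperature of
#' 12.39 degC (54.3 degF) and 345.56 Celsius degree-days (622 degF
#' degree-days) per generation, with quarantine spanning three generations.
#'
#' @param base_temp Base development temperature, degC.
#' @param dd_per_generation Thermal requirement per generation, DDc.
#' @param n_generations Number of generations the quarantine must cover.
#' @param method Daily degree-day estimator: `"single_sine"` (closed-form
#'   sinusoid between tmin and tmax) or `"hourly_sum"` (simple summation of
#'   hourly exceedances).
#' @param upper_cutoff Optional horizontal upper developmental cutoff, degC;
#'   `NULL` (the default) disables it, matching the regulatory calculation
#'   which specifies only a base temperature.
#' @return A list of class `degree_day_model`.
#' @export
degree_day_model <- function(base_temp = 12.39, dd_per_generation = 345.56,
                             n_generations = 3L,
                             method = c("single_sine", "hourly_sum"),
                             upper_cutoff = NULL) {
  stopifnot(dd_per_generation > 0, n_generations >= 1)
  method <- match.arg(method)
  structure(list(base_temp = base_temp, dd_per_generation = dd_per_generation,
                 n_generations = as.integer(n_generations), method = method,
                 upper_cutoff = upper_cutoff),
            class = "degree_day_model")
}

# area per day between the daily sinusoid and a horizontal threshold
sine_area_above <- function(tmin, tmax, thresh) {
  m <- (tmin + tmax) / 2
  a <- (tmax - tmin) / 2
  thresh <- rep_len(thresh, length(m))
  out <- numeric(length(m))
  below <- tmax <= thresh
  above <- tmin >= thresh
  mid <- !below & !above
  out[above] <- (m - thresh)[above]
  if (any(mid)) {
    theta <- asin(pmin(pmax((thresh[mid] - m[mid]) / a[mid], -1), 1))
    out[mid] <- ((m[mid] - thresh[mid]) * (pi / 2 - theta) + a[mid] * cos(theta)) / pi
  }
  out
}

#' Single-sine daily degree-days
#'
#' Closed-form degree-days for one day assuming temperature follows a
#' sinusoid between the day's minimum and maximum. With daily mean
#' `m = (tmin + tmax)/2` and half-amplitude `a = (tmax - tmin)/2`: zero when
#' `tmax <= base`; `m - base` when `tmin >= base`; otherwise
#' `[(m - base)(pi/2 - theta) + a cos(theta)] / pi` with
#' `theta = asin((base - m)/a)`. Vectorised over days.
#'
#' @param tmin,tmax Daily extremes, degC (`tmin <= tmax`), or a tibble with
#'   `tmin`/`tmax` columns passed as `tmin` with `tmax` missing.
#' @param base Base development temperature, degC.
#' @param upper_cutoff Optional horizontal upper cutoff, degC.
#' @return Degree-days (DDc) per day, always >= 0.
#' @export
#' @examples
#' single_sine_dd(6.39, 18.39, base = 12.39)  # mean at base: a / pi
single_sine_dd <- function(tmin, tmax, base = 12.39, upper_cutoff = NULL) {
  if (missing(tmax) && is.data.frame(tmin)) {
    tmax <- tmin$tmax
    tmin <- tmin$tmin
  }
  stopifnot(length(tmin) == length(tmax), all(tmin <= tmax))
  dd <- sine_area_above(tmin, tmax, base)
  if (!is.null(upper_cutoff)) {
    dd <- dd - sine_area_above(tmin, tmax, upper_cutoff)
  }
  pmax(dd, 0)
}

#' Hourly-summation daily degree-days
#'
#' Simple summation over a day's 24 hourly temperatures:
#' `sum(max(T_h - base, 0)) / 24`.
#'
#' @param hours Exactly 24 hourly temperatures, degC.
#' @param base Base development temperature, degC.
#' @return Degree-days (DDc) for the day.
#' @export
hourly_sum_dd <- function(hours, base = 12.39) {
  if (length(hours) != 24L) {
    stop("hourly_sum_dd needs exactly 24 values, got ", length(hours))
  }
  sum(pmax(hours - base, 0)) / 24
}

#' Degree-day predicted quarantine length from a daily series
#'
#' The predicted quarantine length (PQL) is the smallest whole number of
#' days, counting the start date as day 1, whose cumulative degree-days reach
#' the model's total threshold (`n_generations * dd_per_generation`). If the
#' series ends first the record is censored and carries the partial
#' accumulation.
#'
#' @param daily_dd Ordered daily degree-day values beginning on the start date.
#' @param model A [degree_day_model()].
#' @return A one-row tibble: `pql_days` (integer, `NA` when censored),
#'   `censored` (logical), `accum_dd` (degree-days accumulated by `pql_days`,
#'   or by the series end when censored).
#' @export
dd_pql <- function(daily_dd, model = degree_day_model()) {
  if (length(daily_dd) == 0L) stop("empty daily degree-day series")
  threshold <- model$n_generations * model$dd_per_generation
  cum <- cumsum(daily_dd)
  d <- which(cum >= threshold)[1L]
  if (is.na(d)) {
    tibble::tibble(pql_days = NA_integer_, censored = TRUE,
                   accum_dd = cum[length(cum)])
  } else {
    tibble::tibble(pql_days = as.integer(d), censored = FALSE, accum_dd = cum[d])
  }
}

#' Degree-day PQL for every start date in a temperature series
#'
#' Computes the daily degree-day series once (single-sine from daily
#' extremes, or hourly summation from the raw hours) and scans cumulative
#' sums for each start date at the requested spacing. Start dates whose
#' accumulation is not complete by the end of the data are censored, never
#' extrapolated.
#'
#' @param series A gap-free `hourly_temps` tibble.
#' @param model A [degree_day_model()]; its `method` selects the daily
#'   estimator.
#' @param every_days Spacing between successive start dates, days.
#' @return A tibble with `start_date`, `method`, `pql_days`, `censored`,
#'   `accum_dd` — one row per start date.
#' @export
dd_pql_series <- function(series, model = degree_day_model(), every_days = 1L) {
  daily <- daily_degree_days(series, model)
  threshold <- model$n_generations * model$dd_per_generation
  cum <- c(0, cumsum(daily$dd))
  starts <- seq(1L, nrow(daily), by = every_days)
  # smallest j with cum[j+1] - cum[i] >= threshold, i.e. first day index
  # reaching the target accumulation
  target <- cum[starts] + threshold
  pos <- findInterval(target, cum[-1L], left.open = TRUE) + 1L
  censored <- pos > nrow(daily)
  pql <- ifelse(censored, NA_integer_, pos - starts + 1L)
  accum <- ifelse(censored, cum[length(cum)] - cum[starts], cum[pmin(pos + 1L, length(cum))] - cum[starts])
  tibble::tibble(
    start_date = daily$date[starts],
    method = model$method,
    pql_days = as.integer(pql),
    censored = censored,
    accum_dd = accum
  )
}

#' Daily degree-days for each complete day of an hourly series
#'
#' @param series A gap-free `hourly_temps` tibble.
#' @param model A [degree_day_model()].
#' @return A tibble with `date` and `dd`.
#' @export
daily_degree_days <- function(series, model = degree_day_model()) {
  if (model$method == "single_sine") {
    ext <- daily_extremes(series)
    tibble::tibble(date = ext$date,
                   dd = single_sine_dd(ext$tmin, ext$tmax, model$base_temp,
                                       model$upper_cutoff))
  } else {
    d <- tibble::tibble(date = as.Date(series$timestamp, tz = "UTC"),
                        temp_c = series$temp_c)
    d |>
      dplyr::group_by(.data$date) |>
      dplyr::summarise(n = dplyr::n(),
                       dd = sum(pmax(.data$temp_c - model$base_temp, 0)) / 24,
                       .groups = "drop") |>
      dplyr::filter(.data$n == 24L) |>
      dplyr::select("date", "dd")
  }
}

#' Write a PQL table in the standard CSV dialect
#'
#' Header `start_date,method,pql_days,censored`; dates as `YYYY-MM-DD`;
#' `censored` as 0/1 with `pql_days` left empty when censored.
#'
#' @param pql A tibble from [dd_pql_series()] or [run_runset()]'s runs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pql_csv <- function(pql, path) {
  out <- tibble::tibble(
    start_date = format(pql$start_date, "%Y-%m-%d"),
    method = pql$method,
    pql_days = pql$pql_days,
    censored = as.integer(pql$censored)
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
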