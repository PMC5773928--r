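#' Remove temperature outliers by rolling-median deviation
#'
#' Deletes records whose temperature differs from the median of neighbouring
#' records (all records within `window_hours` hours, the record itself
#' excluded) by more than `threshold_c`. This removes isolated sensor spikes
#' without clipping genuine heat waves or cold snaps, which move the local
#' median along with the point.
#'
#' @param raw A tibble with `timestamp` and `temp_c` columns (irregular
#'   spacing allowed).
#' @param window_hours Half-width of the neighbourhood in hours (>= 3).
#' @param threshold_c Maximum allowed deviation from the rolling median, degC.
#' @return The input with outlier rows removed.
#' @export
remove_outliers <- function(raw, window_hours = 24, threshold_c = 15) {
  stopifnot(window_hours >= 3, threshold_c > 0)
  if (nrow(raw) < 3L) {
    warning("fewer than 3 records; outlier screen skipped")
    return(raw)
  }
  t_num <- as.numeric(raw$timestamp)
  med <- rolling_time_median_cpp(t_num, raw$temp_c, window_hours * 3600)
  keep <- is.na(med) | abs(raw$temp_c - med) <= threshold_c
  raw[keep, , drop = FALSE]
}

#' Resample an irregular observation series to a gap-free hourly grid
#'
#' Aligns observations to every hour on the hour. Hours falling inside
#' observation gaps no longer than `large_gap_hours` are filled by linear
#' interpolation in time (`interpolated_small_gap`); hours inside larger gaps
#' are filled per hour-of-day by linear interpolation between the nearest
#' earlier and later days that have an observed or small-gap value at the
#' same hour (`interpolated_day_over_day`). Hours coinciding exactly with a
#' retained observation keep that observation (flag `observed`, or the
#' observation's own flag when the input carries one, which makes the
#' operation idempotent).
#'
#' @param raw A tibble with `timestamp`, `temp_c` and optionally `fill_flag`,
#'   sorted, spanning at least 48 hours.
#' @param large_gap_hours Gaps longer than this many hours switch from
#'   in-time to day-over-day interpolation. Default 3.
#' @param site Optional site metadata attached to the result.
#' @return An `hourly_temps` tibble: `timestamp`, `temp_c`, `fill_flag`.
#' @export
resample_and_fill <- function(raw, large_gap_hours = 3, site = NULL) {
  stopifnot(nrow(raw) >= 2L)
  raw <- dplyr::arrange(raw, .data$timestamp)
  t_obs <- round(as.numeric(raw$timestamp))
  if (anyDuplicated(t_obs)) stop("duplicate timestamps; run read_hourly_csv() or deduplicate first")
  span_h <- (t_obs[length(t_obs)] - t_obs[1L]) / 3600
  if (span_h < 48) stop("series must span at least 48 hours, got ", round(span_h, 1), " h")

  grid <- seq(ceiling(t_obs[1L] / 3600) * 3600,
              floor(t_obs[length(t_obs)] / 3600) * 3600, by = 3600)

  in_flag <- if ("fill_flag" %in% names(raw)) raw$fill_flag else
    rep("observed", nrow(raw))

  # bracket each grid hour between observations
  idx <- findInterval(grid, t_obs)            # t_obs[idx] <= grid < t_obs[idx+1]
  exact <- t_obs[idx] == grid
  temp <- rep(NA_real_, length(grid))
  flag <- rep(NA_character_, length(grid))
  temp[exact] <- raw$temp_c[idx[exact]]
  flag[exact] <- in_flag[idx[exact]]

  inner <- which(!exact)
  if (length(inner)) {
    lo <- idx[inner]
    gap_h <- (t_obs[lo + 1L] - t_obs[lo]) / 3600
    small <- gap_h <= large_gap_hours
    if (any(small)) {
      i <- inner[small]
      l <- idx[i]
      w <- (grid[i] - t_obs[l]) / (t_obs[l + 1L] - t_obs[l])
      temp[i] <- raw$temp_c[l] * (1 - w) + raw$temp_c[l + 1L] * w
      flag[i] <- "interpolated_small_gap"
    }
  }

  # day-over-day fill for hours inside large gaps
  need <- which(is.na(temp))
  if (length(need)) {
    hod <- (grid %% 86400) / 3600
    good <- !is.na(temp)
    for (h in unique(hod[need])) {
      cand <- which(good & hod == h)           # grid positions with a value at this hour
      tgt <- need[hod[need] == h]
      if (!length(cand)) {
        stop("unfillable gap: no bracketing day with a value at hour ",
             h, " for interval ", format_ts(as.POSIXct(min(grid[tgt]), origin = "1970-01-01", tz = "UTC")),
             " .. ", format_ts(as.POSIXct(max(grid[tgt]), origin = "1970-01-01", tz = "UTC")))
      }
      pos <- findInterval(tgt, cand)
      bad <- pos == 0L | pos == length(cand)
      if (any(bad)) {
        b <- tgt[bad][1L]
        stop("unfillable gap touching the series boundary near ",
             format_ts(as.POSIXct(grid[b], origin = "1970-01-01", tz = "UTC")))
      }
      before <- cand[pos]
      after <- cand[pos + 1L]
      w <- (grid[tgt] - grid[before]) / (grid[after] - grid[before])
      temp[tgt] <- temp[before] * (1 - w) + temp[after] * w
      flag[tgt] <- "interpolated_day_over_day"
    }
  }

  out <- new_hourly_temps(
    as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"), temp, flag,
    site = site %||% attr(raw, "site")
  )
  validate_hourly(out)
  out
}

#' Daily temperature extremes from an hourly series
#'
#' One row per complete calendar day (24 hourly values); partial first and
#' last days are excluded to avoid biased extremes.
#'
#' @param series An `hourly_temps` tibble (gap-free, hourly-aligned).
#' @return A tibble with `date`, `tmin`, `tmax`.
#' @export
daily_extremes <- function(series) {
  stopifnot(nrow(series) >= 24L)
  d <- tibble::tibble(
    date = as.Date(series$timestamp, tz = "UTC"),
    temp_c = series$temp_c
  )
  d |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(n = dplyr::n(), tmin = min(.data$temp_c),
                     tmax = max(.data$temp_c), .groups = "drop") |>
    dplyr::filter(.data$n == 24L) |>
    dplyr::select("date", "tmin", "tmax")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
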