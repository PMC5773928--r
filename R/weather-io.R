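FILL_FLAGS <- c("observed", "interpolated_small_gap", "interpolated_day_over_day")

TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

parse_ts <- function(x) {
  as.POSIXct(x, format = TS_FORMAT, tz = "UTC")
}

format_ts <- function(x) {
  format(x, TS_FORMAT, tz = "UTC")
}

#' Read an hourly-temperature CSV file
#'
#' Reads the package's hourly temperature dialect: a header row
#' `timestamp,temp_c[,fill_flag]`, ISO-8601 timestamps
#' (`YYYY-MM-DDTHH:MM:SS`, treated as local standard time with no
#' daylight-saving transitions), and decimal Celsius temperatures. Records
#' are sorted by timestamp; exact duplicate rows are dropped and conflicting
#' duplicates (same timestamp, different temperature) are resolved by their
#' mean.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `timestamp` (POSIXct, UTC-encoded local
#'   standard time), `temp_c`, and `fill_flag` if present in the file.
#' @export
read_hourly_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) stop("empty input: ", path, " contains no records")
  required <- c("timestamp", "temp_c")
  missing <- setdiff(required, names(raw))
  if (length(missing)) stop("missing required column(s): ", paste(missing, collapse = ", "))

  ts <- parse_ts(raw$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop(sprintf("parse error at line %d: malformed timestamp '%s'",
                 bad + 1L, raw$timestamp[bad]))
  }
  temp <- suppressWarnings(as.numeric(raw$temp_c))
  if (anyNA(temp)) {
    bad <- which(is.na(temp))[1L]
    stop(sprintf("parse error at line %d: non-numeric temperature '%s'",
                 bad + 1L, raw$temp_c[bad]))
  }

  out <- tibble::tibble(timestamp = ts, temp_c = temp)
  if ("fill_flag" %in% names(raw)) {
    flag <- raw$fill_flag
    if (!all(flag %in% FILL_FLAGS)) {
      bad <- which(!flag %in% FILL_FLAGS)[1L]
      stop(sprintf("parse error at line %d: unknown fill_flag '%s'",
                   bad + 1L, flag[bad]))
    }
    out$fill_flag <- flag
  }

  out <- dplyr::arrange(out, .data$timestamp)
  # exact duplicates collapse; conflicting duplicates resolve by mean
  out <- out |>
    dplyr::group_by(.data$timestamp) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of("fill_flag"), ~ .x[1L]),
      temp_c = mean(.data$temp_c),
      .groups = "drop"
    ) |>
    dplyr::select(dplyr::all_of(c("timestamp", "temp_c")), dplyr::any_of("fill_flag"))
  out
}

#' Write an hourly-temperature CSV file
#'
#' Writes the hourly dialect with all three columns; `fill_flag` defaults to
#' `"observed"` when absent from the input.
#'
#' @param series A tibble with `timestamp`, `temp_c`, and optionally
#'   `fill_flag` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hourly_csv <- function(series, path) {
  stopifnot(all(c("timestamp", "temp_c") %in% names(series)))
  flag <- if ("fill_flag" %in% names(series)) series$fill_flag else
    rep("observed", nrow(series))
  out <- tibble::tibble(
    timestamp = format_ts(series$timestamp),
    temp_c = series$temp_c,
    fill_flag = flag
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

new_hourly_temps <- function(timestamp, temp_c, fill_flag, site = NULL) {
  out <- tibble::tibble(timestamp = timestamp, temp_c = temp_c, fill_flag = fill_flag)
  attr(out, "site") <- site
  class(out) <- c("hourly_temps", class(out))
  out
}

#' Validate an hourly temperature series
#'
#' Checks the gap-free hourly contract: timestamps exactly one hour apart,
#' finite temperatures, and one recognised fill flag per hour.
#'
#' @param series A tibble with `timestamp`, `temp_c`, `fill_flag`.
#' @return `series`, invisibly, if valid; otherwise an error.
#' @export
validate_hourly <- function(series) {
  stopifnot(all(c("timestamp", "temp_c", "fill_flag") %in% names(series)))
  if (nrow(series) > 1L) {
    dt <- diff(as.numeric(series$timestamp))
    if (any(dt != 3600)) stop("timestamps are not consecutive hours")
  }
  if (!all(is.finite(series$temp_c))) stop("non-finite temperatures present")
  if (!all(series$fill_flag %in% FILL_FLAGS)) stop("unrecognised fill_flag value")
  invisible(series)
}
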