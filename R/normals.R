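#' Day-of-year normals without smoothing
#'
#' Climatological "normals": all values sharing a calendar day (month, day)
#' are aggregated across years, with no running-mean smoothing. February 29
#' is kept as its own key (with a smaller sample count) rather than merged
#' into February 28.
#'
#' @param dated_values A tibble with a `date` column (Date) and a `value`
#'   column, or a two-column data frame in that order.
#' @param sigma `"population"` (divisor n, the default — consistent with
#'   min/max being population summaries) or `"sample"` (divisor n-1).
#' @return A tibble with `month`, `day`, `n`, `mean`, `min`, `max`, `std`,
#'   `q25`, `median`, `q75`, sorted by calendar day. Quartiles use the
#'   linear-interpolation convention between order statistics.
#' @export
compute_normals <- function(dated_values, sigma = c("population", "sample")) {
  sigma <- match.arg(sigma)
  stopifnot(nrow(dated_values) >= 1L)
  if (!all(c("date", "value") %in% names(dated_values))) {
    names(dated_values)[1:2] <- c("date", "value")
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sd_fun <- if (sigma == "population") pop_sd else sd
  dated_values |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(
      month = as.integer(format(.data$date, "%m")),
      day = as.integer(format(.data$date, "%d"))
    ) |>
    dplyr::group_by(.data$month, .data$day) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      std = sd_fun(.data$value),
      q25 = unname(quantile(.data$value, 0.25, type = 7)),
      median = unname(quantile(.data$value, 0.5, type = 7)),
      q75 = unname(quantile(.data$value, 0.75, type = 7)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$month, .data$day)
}

#' Fraction of variance captured by the mean of the normal
#'
#' Variance decomposition of a dated series against its own day-of-year mean
#' normal: `R^2 = 1 - sum((y - yhat_doy)^2) / sum((y - ybar)^2)`, where
#' `yhat_doy` is the normal mean for each value's calendar day and `ybar` the
#' grand mean. Reported as a percentage.
#'
#' @param dated_values A tibble with `date` and `value` columns.
#' @param normals Output of [compute_normals()] built from the same kind of
#'   series; defaults to normals of `dated_values` themselves.
#' @return R-squared as a percentage (0-100 when normals come from the same
#'   series).
#' @export
normal_r2 <- function(dated_values, normals = compute_normals(dated_values)) {
  if (!all(c("date", "value") %in% names(dated_values))) {
    names(dated_values)[1:2] <- c("date", "value")
  }
  d <- dated_values |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(
      month = as.integer(format(.data$date, "%m")),
      day = as.integer(format(.data$date, "%d"))
    ) |>
    dplyr::left_join(dplyr::select(normals, "month", "day", doy_mean = "mean"),
                     by = c("month", "day"))
  if (anyNA(d$doy_mean)) stop("normals are missing some calendar days present in the data")
  ss_tot <- sum((d$value - mean(d$value))^2)
  if (ss_tot == 0) stop("zero total variance: R-squared undefined")
  ss_res <- sum((d$value - d$doy_mean)^2)
  100 * (1 - ss_res / ss_tot)
}

#' Write a normals table in the standard CSV dialect
#'
#' @param normals Output of [compute_normals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_normals_csv <- function(normals, path) {
  readr::write_csv(normals, path, progress = FALSE)
  invisible(path)
}
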