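#' Ordinary least squares of site median PQL on latitude
#'
#' Fits `median_pql ~ latitude` across sites and reports the slope
#' (days per degree of latitude), intercept, and the regression's overall
#' F-test.
#'
#' @param site_medians A data frame with columns `latitude` and `median_pql`
#'   (one row per site, >= 3 sites).
#' @return A list of class `latitude_fit`: `slope`, `intercept`, `F`, `p`,
#'   `n_sites`.
#' @export
latitude_ols <- function(site_medians) {
  stopifnot(all(c("latitude", "median_pql") %in% names(site_medians)))
  n <- nrow(site_medians)
  if (n < 3L) stop("need at least 3 sites, got ", n)
  if (length(unique(site_medians$latitude)) == 1L) {
    stop("singular fit: all latitudes identical")
  }
  fit <- lm(median_pql ~ latitude, data = site_medians)
  s <- summary(fit)
  fstat <- s$fstatistic
  p <- unname(pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE))
  structure(list(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    F = unname(fstat[1L]),
    p = p,
    n_sites = n
  ), class = "latitude_fit")
}

#' Nearest weather station to an outbreak location
#'
#' Minimises great-circle (haversine) distance; ties are broken by lower
#' latitude, then by callsign order.
#'
#' @param q A one-row data frame (or list) with `latitude` and `longitude`.
#' @param sites A site table like [medfly_sites()] with `callsign`,
#'   `latitude`, `longitude`.
#' @return The matching row of `sites`.
#' @export
nearest_site <- function(q, sites) {
  stopifnot(nrow(sites) >= 1L)
  d <- geosphere::distHaversine(
    c(q$longitude[1L], q$latitude[1L]),
    cbind(sites$longitude, sites$latitude)
  )
  tol <- max(1e-9, min(d) * 1e-12)
  tied <- which(d <= min(d) + tol)
  pick <- tied[order(sites$latitude[tied], sites$callsign[tied])][1L]
  sites[pick, , drop = FALSE]
}

#' Paired comparison of degree-day and agent-based quarantine lengths
#'
#' For matched (same date and site) quarantine-length pairs: a paired t-test
#' on the method difference, and an F-test comparing each method's
#' variability around its own day-of-year normal mean (deviation = value
#' minus the mean normal for that calendar day).
#'
#' @param dd A tibble with `date` and `value` (degree-day PQLs).
#' @param abs A tibble with `date` and `value` (agent-based PQLs), paired
#'   row-by-row with `dd`.
#' @param dd_normals,abs_normals [compute_normals()] tables supplying each
#'   method's day-of-year mean.
#' @param alternative For the variance-ratio test: `"two.sided"` (default;
#'   equivalent to mirroring the larger variance into the numerator) or a
#'   one-sided alternative on `var(dd deviations) / var(abs deviations)`.
#' @return A list of class `paired_comparison`: `n`, `mean_dd`, `sd_dd`,
#'   `mean_abs`, `sd_abs`, `t`, `df`, `p`, `dev_sd_dd`, `dev_sd_abs`, `F`,
#'   `F_df`, `F_p`.
#' @export
paired_comparison <- function(dd, abs, dd_normals, abs_normals,
                              alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(nrow(dd) == nrow(abs), nrow(dd) >= 2L)

  diff <- dd$value - abs$value
  n <- length(diff)
  if (sd(diff) == 0) {
    # degenerate pairs: identical lists give t = 0, p = 1; a constant nonzero
    # difference is infinitely significant
    t_stat <- if (mean(diff) == 0) 0 else sign(mean(diff)) * Inf
    tt <- list(statistic = t_stat, parameter = n - 1L,
               p.value = if (mean(diff) == 0) 1 else 0)
  } else {
    tt <- t.test(dd$value, abs$value, paired = TRUE)
  }

  doy_mean <- function(x, normals) {
    key <- paste(as.integer(format(x$date, "%m")), as.integer(format(x$date, "%d")))
    nk <- paste(normals$month, normals$day)
    m <- normals$mean[match(key, nk)]
    if (anyNA(m)) stop("normals are missing some calendar days present in the pairs")
    m
  }
  dev_dd <- dd$value - doy_mean(dd, dd_normals)
  dev_abs <- abs$value - doy_mean(abs, abs_normals)
  if (var(dev_abs) == 0) stop("zero deviation variance in the denominator")
  vt <- var.test(dev_dd, dev_abs, alternative = alternative)

  structure(list(
    n = nrow(dd),
    mean_dd = mean(dd$value), sd_dd = sd(dd$value),
    mean_abs = mean(abs$value), sd_abs = sd(abs$value),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    dev_sd_dd = sd(dev_dd), dev_sd_abs = sd(dev_abs),
    F = unname(vt$statistic), F_df = unname(vt$parameter), F_p = vt$p.value
  ), class = "paired_comparison")
}
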