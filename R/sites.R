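#' Construct weather-station site metadata
#'
#' @param callsign Four-character station callsign (e.g. `"KFAT"`).
#' @param name Free-text station name.
#' @param latitude Degrees north, in `[-90, 90]`.
#' @param longitude Degrees east, in `[-180, 180]`.
#' @param elevation Elevation in metres.
#' @param start_year First calendar year of usable data.
#'
#' @return A one-row tibble of class `site_meta`.
#' @export
#' @examples
#' site_meta("KFAT", "FRESNO YOSEMITE INTERNATIONAL", 36.780, -119.719, 101.5, 1950)
site_meta <- function(callsign, name, latitude, longitude, elevation = NA_real_,
                      start_year = NA_integer_) {
  stopifnot(is.character(callsign), nchar(callsign) == 4L)
  if (!is.finite(latitude) || latitude < -90 || latitude > 90) {
    stop("latitude must be in [-90, 90], got ", latitude)
  }
  if (!is.finite(longitude) || longitude < -180 || longitude > 180) {
    stop("longitude must be in [-180, 180], got ", longitude)
  }
  out <- tibble::tibble(
    callsign = callsign, name = name,
    latitude = as.numeric(latitude), longitude = as.numeric(longitude),
    elevation = as.numeric(elevation), start_year = as.integer(start_year)
  )
  class(out) <- c("site_meta", class(out))
  out
}

#' Reference weather-station table for the 11 study sites
#'
#' NOAA Integrated Surface Database airport stations spanning the latitudinal
#' range of Medfly suitability in the continental United States: six
#' California sites (coastal to arid inland), one Texas, and four Florida
#' sites. Eight stations have usable hourly data from 1950; IAH starts in
#' 1970 and BUR and MCO in 1973 because of multi-week gaps in earlier years.
#'
#' @return A tibble with columns `callsign`, `name`, `state`, `latitude`,
#'   `longitude`, `elevation` (m) and `start_year`.
#' @export
#' @examples
#' medfly_sites()
medfly_sites <- function() {
  tibble::tribble(
    ~callsign, ~name,                             ~state, ~latitude, ~longitude, ~elevation, ~start_year,
    "KSFO", "SAN FRANCISCO INTERNATIONAL A",      "CA",   37.620,  -122.365,   2.4, 1950L,
    "KFAT", "FRESNO YOSEMITE INTERNATIONAL",      "CA",   36.780,  -119.719, 101.5, 1950L,
    "KBUR", "BURBANK-GLENDALE-PASA ARPT",         "CA",   34.201,  -118.358, 236.2, 1973L,
    "KLAX", "LOS ANGELES INTERNATIONAL AIR",      "CA",   33.938,  -118.389,  29.6, 1950L,
    "KRIV", "MARCH AIR RESERVE BASE",             "CA",   33.900,  -117.250, 468.2, 1950L,
    "KSAN", "SAN DIEGO INTERNATIONAL AIRPO",      "CA",   32.734,  -117.183,   4.6, 1950L,
    "KJAX", "JACKSONVILLE INTERNATIONAL A",       "FL",   30.495,   -81.694,   7.9, 1950L,
    "KIAH", "G BUSH INTERCONTINENTAL AP/HO",      "TX",   29.980,   -95.360,  29.0, 1970L,
    "KMCO", "ORLANDO INTERNATIONAL AIRPORT",      "FL",   28.434,   -81.325,  27.4, 1973L,
    "KTPA", "TAMPA INTERNATIONAL AIRPORT",        "FL",   27.962,   -82.540,   5.8, 1950L,
    "KMIA", "MIAMI INTERNATIONAL AIRPORT",        "FL",   25.791,   -80.316,   8.8, 1950L
  )
}
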