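STAGES <- c("egg", "larva", "pupa", "immature_adult", "mature_adult")
MATED_LEVELS <- c("unmated", "fertile_mated", "sterile_mated")

#' Biological parameter ranges for the elimination simulator
#'
#' Lower/upper bounds for every parameter sampled by the Latin hypercube
#' sweep. The outbreak and intervention ranges follow estimates for a typical
#' California response: 33-100 initial adult females, a 0.5-1 daily chance
#' that sterile-male releases void a female's reproduction, and 0.05-0.15
#' additional daily mortality from control efforts. Stage-level thermal and
#' mortality ranges are calibrated placeholders: their midpoints sum to
#' 345.56 DDc of development above a 12.39 degC base, keeping the simulator
#' commensurable with the regulatory degree-day model.
#'
#' @param ... Named overrides; each value is a numeric `c(low, high)` pair
#'   (a single number fixes the parameter).
#' @return A tibble of class `bio_param_ranges` with columns `param`, `low`,
#'   `high`.
#' @export
#' @examples
#' bio_param_ranges(p_sit_daily = c(0.9, 1))
bio_param_ranges <- function(...) {
  defaults <- list(
    n_initial_females = c(33, 100),
    p_sit_daily = c(0.5, 1.0),
    control_mortality_daily = c(0.05, 0.15),
    dd_egg = c(21, 31),
    dd_larva = c(84, 126),
    dd_pupa = c(128, 192),
    dd_immature_adult = c(44, 65.12),
    base_egg = c(11.39, 13.39),
    base_larva = c(11.39, 13.39),
    base_pupa = c(11.39, 13.39),
    base_immature_adult = c(11.39, 13.39),
    mu_egg = c(0.05, 0.15),
    mu_larva = c(0.05, 0.15),
    mu_pupa = c(0.02, 0.08),
    mu_immature_adult = c(0.03, 0.10),
    mu_mature_adult = c(0.02, 0.08),
    fecundity = c(10, 30),
    cold_lethal_c = c(-6, -2),
    p_cold_hourly = c(0.05, 0.50),
    heat_lethal_c = c(42, 46),
    p_heat_hourly = c(0.05, 0.20)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  for (nm in names(over)) {
    v <- over[[nm]]
    if (length(v) == 1L) v <- c(v, v)
    defaults[[nm]] <- v
  }
  out <- tibble::tibble(
    param = names(defaults),
    low = vapply(defaults, `[`, numeric(1), 1L),
    high = vapply(defaults, `[`, numeric(1), 2L)
  )
  if (any(out$low > out$high)) {
    bad <- out$param[out$low > out$high]
    stop("low > high for: ", paste(bad, collapse = ", "))
  }
  prob <- grepl("^(p_|mu_|control)", out$param)
  if (any(prob & (out$low < 0 | out$high > 1))) {
    stop("probability parameters must lie in [0, 1]")
  }
  if (any(grepl("^dd_", out$param) & out$low <= 0)) {
    stop("per-stage thermal requirements must be positive")
  }
  class(out) <- c("bio_param_ranges", class(out))
  out
}

#' Latin hypercube sample of the biological parameter space
#'
#' Draws `n` parameter vectors so that, for every parameter independently,
#' exactly one sample falls in each of the `n` equal-width strata of its
#' range, with independent seeded permutations across parameters.
#'
#' @param ranges A [bio_param_ranges()] table.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed for the design.
#' @return A tibble with `n` rows and one column per parameter.
#' @export
lhs_sample <- function(ranges, n, seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  k <- nrow(ranges)
  u <- lhs::randomLHS(n, k)
  out <- sweep(u, 2, ranges$high - ranges$low, `*`)
  out <- sweep(out, 2, ranges$low, `+`)
  colnames(out) <- ranges$param
  tibble::as_tibble(out)
}

#' Initialise the outbreak population
#'
#' A "standard outbreak": `n_initial_females` mature unmated adult females
#' (rounded to the nearest integer, at least 1) plus an equal number of
#' mature adult males, all with zero within-stage development. The same fixed
#' age profile is used for every simulation.
#'
#' @param params A one-row parameter tibble (from [lhs_sample()]) or a named
#'   vector containing `n_initial_females`.
#' @return An agent tibble: `stage`, `sex`, `dev_accum`, `mated`, `alive`.
#' @export
init_population <- function(params) {
  nf <- max(1L, as.integer(round(as.numeric(params[["n_initial_females"]]))))
  tibble::tibble(
    stage = rep("mature_adult", 2L * nf),
    sex = rep(c("F", "M"), each = nf),
    dev_accum = 0,
    mated = "unmated",
    alive = TRUE
  )
}

params_to_vector <- function(params) {
  if (is.data.frame(params)) {
    stopifnot(nrow(params) == 1L)
    params <- unlist(params[1L, , drop = TRUE])
  }
  params
}

agents_to_codes <- function(agents) {
  list(
    stage = match(agents$stage, STAGES) - 1L,
    sex = dplyr::case_match(agents$sex, "F" ~ 0L, "M" ~ 1L, .default = -1L),
    dev = as.numeric(agents$dev_accum),
    mated = match(agents$mated, MATED_LEVELS) - 1L,
    alive = agents$alive
  )
}

codes_to_agents <- function(x) {
  tibble::tibble(
    stage = STAGES[x$stage + 1L],
    sex = dplyr::case_match(x$sex, 0L ~ "F", 1L ~ "M", .default = NA_character_),
    dev_accum = x$dev_accum,
    mated = MATED_LEVELS[x$mated + 1L],
    alive = x$alive
  )
}

#' Advance the agent population one day
#'
#' Applies the fixed daily event order: (1) hourly degree-day development
#' with stage advancement (sex assigned at adult emergence); (2) hourly acute
#' cold/heat mortality; (3) daily baseline mortality combined with control
#' mortality as independent hazards; (4) mating, with daily sterilisation at
#' `p_sit_daily` drawn before fertile mating; (5) oviposition by fertile
#' females, Poisson with mean `fecundity * dev_scale(mean temp)`. Newly laid
#' eggs are appended; the dead are retained with `alive = FALSE`.
#'
#' @param agents Agent tibble (see [init_population()]).
#' @param day_hours The day's 24 hourly temperatures, degC.
#' @param params One-row parameter tibble or named vector.
#' @return The updated agent tibble.
#' @export
step_day <- function(agents, day_hours, params) {
  stopifnot(length(day_hours) == 24L)
  p <- params_to_vector(params)
  z <- agents_to_codes(agents)
  out <- sim_step_day_cpp(z$stage, z$sex, z$dev, z$mated, z$alive,
                          as.numeric(day_hours), p)
  codes_to_agents(out)
}

#' Run one elimination simulation
#'
#' Iterates [step_day()] from `start_date` until the last agent dies, the
#' horizon `max_days` is reached, or the temperature data end. Randomness is
#' drawn from R's RNG stream; seed with `set.seed()` for reproducibility.
#'
#' @param series A gap-free `hourly_temps` tibble covering `start_date`.
#' @param start_date Date on which the simulation starts (day 1).
#' @param params One-row parameter tibble or named vector.
#' @param max_days Maximum days simulated before censoring.
#' @param agents Optional initial population; defaults to
#'   [init_population()] from `params`.
#' @param max_population Guard for non-eliminating parameter corners: a
#'   population exceeding this count is clearly not being eradicated and the
#'   simulation is censored instead of growing without bound.
#' @return A one-row tibble: `elimination_day` (days from start, 1-based; 0
#'   for an initially empty population; `NA` when censored), `censored`,
#'   `peak_population`.
#' @export
run_simulation <- function(series, start_date, params, max_days = 730L,
                           agents = NULL, max_population = 100000L) {
  stopifnot(max_days >= 1)
  start_date <- as.Date(start_date)
  start_hour <- start_hour_index(series, start_date)
  run_simulation_at(series$temp_c, start_hour, params, max_days, agents,
                    max_population)
}

# hour index (1-based) of midnight on start_date, or error
start_hour_index <- function(series, start_date) {
  t0 <- as.POSIXct(paste(format(start_date), "00:00:00"), tz = "UTC")
  start_hour <- match(as.numeric(t0), as.numeric(series$timestamp))
  if (is.na(start_hour) || nrow(series) - start_hour + 1L < 24L) {
    stop("start_date ", format(start_date), " not covered by the series")
  }
  start_hour
}

run_simulation_at <- function(temps, start_hour, params, max_days,
                              agents = NULL, max_population = 100000L) {
  p <- params_to_vector(params)
  if (is.null(agents)) agents <- init_population(p)
  z <- agents_to_codes(agents)
  res <- sim_run_cpp(temps, start_hour - 1L, as.integer(max_days),
                     z$stage, z$sex, z$dev, z$mated, z$alive, p,
                     as.integer(max_population))
  tibble::tibble(
    elimination_day = res$elimination_day,
    censored = res$censored,
    peak_population = res$peak_population
  )
}

#' 95%-elimination quarantine length from a run's outcomes
#'
#' The smallest day `d` such that at least `ceiling(quantile * n)` of the
#' run's simulations are eliminated by day `d`; censored when too few
#' simulations reached elimination before the data or horizon ended.
#'
#' @param outcomes Tibble with `elimination_day` and `censored` columns (one
#'   row per simulation).
#' @param quantile Required eliminated fraction; default 0.95.
#' @return A one-row tibble: `abs_pql` (integer days or `NA`), `censored`.
#' @export
abs_pql_from_run <- function(outcomes, quantile = 0.95) {
  n <- nrow(outcomes)
  if (n == 0L) stop("no simulation outcomes")
  k <- ceiling(quantile * n)
  elim <- sort(outcomes$elimination_day[!outcomes$censored])
  if (length(elim) < k) {
    tibble::tibble(abs_pql = NA_integer_, censored = TRUE)
  } else {
    tibble::tibble(abs_pql = as.integer(elim[k]), censored = FALSE)
  }
}

#' Run an ensemble of elimination runs across start dates
#'
#' Starts a run every `every_days` days over the series. Each run draws a
#' fresh seeded Latin hypercube design of `n_sims` parameter vectors and one
#' simulation per vector; its ABS PQL is the 95%-elimination day
#' ([abs_pql_from_run()]). Per-run and per-simulation seeds are pre-drawn
#' from the master seed, so results do not depend on execution order. The
#' 7-day-spaced PQL knots are upsampled to daily values by linear
#' interpolation; censored knots break the interpolation (no bridging).
#'
#' @param series A gap-free `hourly_temps` tibble.
#' @param every_days Spacing between run start dates, days; default 7.
#' @param n_sims Simulations per run (>= 20).
#' @param ranges A [bio_param_ranges()] table.
#' @param seed Master integer seed.
#' @param quantile Elimination fraction defining the PQL; default 0.95.
#' @param max_days Simulation horizon per run, days.
#' @param keep_outcomes Keep the per-simulation outcome table? Default FALSE.
#' @return A list of class `runset`: `runs` (tibble `start_date`, `method`,
#'   `pql_days`, `censored`, `n_sims`), `daily_pql` (tibble `date`,
#'   `pql_days` with `NA` across censored knots), `outcomes` (optional),
#'   `site`, `seed`.
#' @export
run_runset <- function(series, every_days = 7L, n_sims = 250L,
                       ranges = bio_param_ranges(), seed = 1L,
                       quantile = 0.95, max_days = 730L,
                       keep_outcomes = FALSE) {
  stopifnot(n_sims >= 20)
  # complete days only: a start needs at least one full day of data
  full <- daily_extremes(series)$date
  starts <- full[seq(1L, length(full), by = every_days)]

  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, length(starts))

  runs <- vector("list", length(starts))
  outcomes <- if (keep_outcomes) vector("list", length(starts)) else NULL

  temps <- series$temp_c
  for (r in seq_along(starts)) {
    start_hour <- start_hour_index(series, starts[r])
    design <- lhs_sample(ranges, n_sims, seed = run_seeds[r])
    design_m <- as.matrix(design)
    set.seed(run_seeds[r])
    sim_seeds <- sample.int(.Machine$integer.max, n_sims)
    out <- vector("list", n_sims)
    for (j in seq_len(n_sims)) {
      set.seed(sim_seeds[j])
      out[[j]] <- run_simulation_at(temps, start_hour, design_m[j, ],
                                    max_days = max_days)
    }
    out <- dplyr::bind_rows(out, .id = "sim_index")
    pql <- abs_pql_from_run(out, quantile)
    runs[[r]] <- tibble::tibble(
      start_date = starts[r], method = "abs",
      pql_days = pql$abs_pql, censored = pql$censored, n_sims = n_sims
    )
    if (keep_outcomes) {
      out$start_date <- starts[r]
      outcomes[[r]] <- out
    }
  }
  runs <- dplyr::bind_rows(runs)

  structure(list(
    runs = runs,
    daily_pql = upsample_daily(runs),
    outcomes = if (keep_outcomes) dplyr::bind_rows(outcomes) else NULL,
    site = attr(series, "site"),
    seed = seed
  ), class = "runset")
}

#' Upsample PQL knots to a daily series by linear interpolation
#'
#' Interpolates between adjacent uncensored knots only; days between a
#' censored knot and its neighbours are `NA`.
#'
#' @param runs Tibble with `start_date`, `pql_days`, `censored`.
#' @return A tibble with `date` and `pql_days` (numeric, `NA` where broken).
#' @export
upsample_daily <- function(runs) {
  runs <- dplyr::arrange(runs, .data$start_date)
  if (nrow(runs) == 0L) return(tibble::tibble(date = as.Date(character()), pql_days = numeric()))
  days <- seq(runs$start_date[1L], runs$start_date[nrow(runs)], by = "day")
  val <- rep(NA_real_, length(days))
  knot_pos <- match(runs$start_date, days)
  ok <- !runs$censored
  val[knot_pos[ok]] <- runs$pql_days[ok]
  if (nrow(runs) > 1L) {
    for (i in seq_len(nrow(runs) - 1L)) {
      if (runs$censored[i] || runs$censored[i + 1L]) next
      a <- knot_pos[i]; b <- knot_pos[i + 1L]
      if (b - a > 1L) {
        w <- seq_len(b - a - 1L) / (b - a)
        val[(a + 1L):(b - 1L)] <- runs$pql_days[i] * (1 - w) + runs$pql_days[i + 1L] * w
      }
    }
  }
  tibble::tibble(date = days, pql_days = val)
}
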