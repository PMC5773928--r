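test_that("Latin hypercube designs are stratified in every margin", {
  r <- bio_param_ranges()
  for (n in c(4L, 25L)) {
    x <- lhs_sample(r, n, seed = 10 + n)
    for (k in seq_len(nrow(r))) {
      lo <- r$low[k]; hi <- r$high[k]
      strata <- if (hi > lo) floor((x[[r$param[k]]] - lo) / (hi - lo) * n) else rep(0, n)
      strata <- pmin(strata, n - 1)  # the upper endpoint belongs to the top stratum
      if (hi > lo) {
        expect_equal(sort(strata), 0:(n - 1))
      } else {
        expect_true(all(x[[r$param[k]]] == lo))
      }
    }
  }
  # degenerate range: all samples at the fixed value
  rd <- bio_param_ranges(fecundity = 20)
  xd <- lhs_sample(rd, 10, seed = 4)
  expect_true(all(xd$fecundity == 20))
})

test_that("empirical margins of a 100-point design are within 1/n of uniform", {
  r <- bio_param_ranges()
  n <- 100L
  x <- lhs_sample(r, n, seed = 77)
  for (k in c("p_sit_daily", "fecundity", "dd_larva")) {
    lo <- r$low[r$param == k]; hi <- r$high[r$param == k]
    u <- sort((x[[k]] - lo) / (hi - lo))
    gap <- max(abs(u - (seq_len(n) - 0.5) / n))
    expect_lte(gap, 1 / n)
  }
})

test_that("initial populations are paired mature adults", {
  for (nf in c(33, 100)) {
    a <- init_population(c(n_initial_females = nf))
    expect_equal(nrow(a), 2 * nf)
    expect_equal(sum(a$sex == "F"), nf)
    expect_equal(sum(a$sex == "M"), nf)
    expect_true(all(a$stage == "mature_adult"))
    expect_true(all(a$alive))
    expect_true(all(a$dev_accum == 0))
    expect_true(all(a$mated == "unmated"))
  }
})

test_that("a fully lethal cold day kills every agent", {
  p <- fixed_bio_params(p_cold_hourly = 1, cold_lethal_c = 2)
  a <- init_population(p)
  out <- step_day(a, rep(-5, 24), p)
  expect_true(all(!out$alive))
})

test_that("complete sterilisation closes reproduction", {
  p <- fixed_bio_params(p_sit_daily = 1)
  a <- init_population(p)
  set.seed(1)
  for (d in 1:10) {
    a <- step_day(a, rep(25, 24), p)
    expect_lte(nrow(a), 2 * round(p[["n_initial_females"]]))
    expect_true(all(a$stage == "mature_adult"))  # no eggs ever
  }
  expect_true(all(a$mated[a$alive & a$sex == "F"] %in% c("sterile_mated", "unmated")))
})

test_that("an egg accumulates half its requirement per day at +12 degC", {
  p <- fixed_bio_params(dd_egg = 24, base_egg = 12.39, mu_egg = 0,
                        control_mortality_daily = 0, p_cold_hourly = 0,
                        p_heat_hourly = 0)
  egg <- tibble::tibble(stage = "egg", sex = NA_character_, dev_accum = 0,
                        mated = "unmated", alive = TRUE)
  day <- rep(24.39, 24)  # 12 DDc per day above the egg base
  one <- step_day(egg, day, p)
  expect_identical(one$stage, "egg")
  expect_equal(one$dev_accum, 12)
  two <- step_day(one, day, p)
  expect_identical(two$stage, "larva")
  expect_equal(two$dev_accum, 0)
})

test_that("an empty or immediately doomed population ends at day 0 or 1", {
  s <- constant_series(25, n_days = 40)
  p <- fixed_bio_params()
  empty <- init_population(p)[0, ]
  r0 <- run_simulation(s, "2010-01-02", p, agents = empty)
  expect_equal(r0$elimination_day, 0)
  snap <- inject_cold_snap(s, s$timestamp[25], 24, -30)
  p1 <- fixed_bio_params(p_cold_hourly = 1)
  r1 <- run_simulation(snap, "2010-01-02", p1)
  expect_equal(r1$elimination_day, 1)
  expect_error(run_simulation(s, "2011-01-01", p), "not covered")
})

test_that("with sterile-only matings the mean elimination day matches the closed form", {
  s <- constant_series(25, n_days = 400)
  p <- fixed_bio_params(p_sit_daily = 1, n_initial_females = 50)
  q <- 1 - (1 - p[["mu_mature_adult"]]) * (1 - p[["control_mortality_daily"]])
  want <- oracle_pure_death_mean(100, q)
  set.seed(31)
  elim <- replicate(300, run_simulation(s, "2010-01-02", p)$elimination_day)
  expect_false(anyNA(elim))
  se <- sd(elim) / sqrt(length(elim))
  expect_lt(abs(mean(elim) - want), 3 * se)
})

test_that("with reproduction the agent model matches an independent cohort simulation", {
  s <- constant_series(25, n_days = 1000)
  p <- fixed_bio_params(p_sit_daily = 0.8, n_initial_females = 40,
                        control_mortality_daily = 0.15)
  set.seed(55)
  elim_agent <- replicate(200, run_simulation(s, "2010-01-02", p, max_days = 990)$elimination_day)
  elim_cohort <- replicate(200, oracle_cohort_sim(p, 25))
  expect_false(anyNA(elim_agent))
  expect_false(anyNA(elim_cohort))
  se <- sqrt(var(elim_agent) / 200 + var(elim_cohort) / 200)
  expect_lt(abs(mean(elim_agent) - mean(elim_cohort)), 3 * se)
})

test_that("raising control mortality shortens eliminations in distribution", {
  s <- constant_series(25, n_days = 500)
  lo <- fixed_bio_params(control_mortality_daily = 0.05, p_sit_daily = 0.95)
  hi <- fixed_bio_params(control_mortality_daily = 0.15, p_sit_daily = 0.95)
  set.seed(91)
  e_lo <- replicate(150, run_simulation(s, "2010-01-02", lo)$elimination_day)
  e_hi <- replicate(150, run_simulation(s, "2010-01-02", hi)$elimination_day)
  expect_lt(mean(e_hi), mean(e_lo))
  expect_lte(quantile(e_hi, 0.95), quantile(e_lo, 0.95))
})

test_that("the 95% rule is the corresponding order statistic", {
  out <- tibble::tibble(elimination_day = 1:20, censored = FALSE)
  expect_equal(abs_pql_from_run(out)$abs_pql, 19L)  # ceil(0.95*20) = 19
  out7 <- tibble::tibble(elimination_day = rep(7L, 10), censored = FALSE)
  expect_equal(abs_pql_from_run(out7)$abs_pql, 7L)
  # censoring: with fewer than ceil(q*n) uncensored outcomes the run censors
  outc <- tibble::tibble(elimination_day = c(1:18, NA, NA),
                         censored = c(rep(FALSE, 18), TRUE, TRUE))
  expect_true(abs_pql_from_run(outc)$censored)
  expect_error(abs_pql_from_run(outc[0, ]), "no simulation")
})

test_that("the 95% rule matches a sort-based oracle on 2500 simulated days", {
  set.seed(12)
  days <- as.integer(ceiling(rexp(2500, 1 / 80)))
  out <- tibble::tibble(elimination_day = days, censored = FALSE)
  got <- abs_pql_from_run(out)$abs_pql
  want <- sort(days)[ceiling(0.95 * 2500)]
  expect_equal(got, want)
  # smallest d with count(<= d) >= k, verified directly
  expect_gte(sum(days <= got), ceiling(0.95 * 2500))
  expect_lt(sum(days <= got - 1L), ceiling(0.95 * 2500))
})

test_that("upsampling interpolates linearly and never bridges censored knots", {
  runs <- tibble::tibble(
    start_date = as.Date("2010-01-01") + c(0, 7, 14),
    pql_days = c(100L, 107L, NA),
    censored = c(FALSE, FALSE, TRUE)
  )
  up <- upsample_daily(runs)
  expect_equal(up$pql_days[up$date == as.Date("2010-01-04")], 103)
  expect_true(all(is.na(up$pql_days[up$date > as.Date("2010-01-08")])))
  single <- upsample_daily(runs[1, ])
  expect_equal(nrow(single), 1L)
  expect_equal(single$pql_days, 100)
})

test_that("a runset is reproducible bit-for-bit from its seed", {
  w <- generate_synthetic_weather(quiet_climate(seed = 2, annual_mean = 22), n_years = 1)
  a <- run_runset(w$clean, every_days = 120, n_sims = 20, seed = 14, max_days = 200)
  b <- run_runset(w$clean, every_days = 120, n_sims = 20, seed = 14, max_days = 200)
  expect_identical(a$runs, b$runs)
  fa <- tempfile(); fb <- tempfile()
  write_pql_csv(a$runs, fa); write_pql_csv(b$runs, fb)
  expect_identical(readLines(fa), readLines(fb))
})
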