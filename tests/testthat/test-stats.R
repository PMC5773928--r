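test_that("latitude regression recovers exact and null relationships", {
  sm <- tibble::tibble(latitude = c(26, 30, 34, 38),
                       median_pql = 5 * c(26, 30, 34, 38) + 3)
  fit <- latitude_ols(sm)
  expect_equal(fit$slope, 5, tolerance = 1e-10)
  expect_equal(fit$intercept, 3, tolerance = 1e-8)
  expect_lt(fit$p, 1e-10)
  set.seed(6)
  null <- tibble::tibble(latitude = seq(25, 40, length.out = 11),
                         median_pql = rnorm(11, 150, 20))
  expect_gt(latitude_ols(null)$p, 0.01)
  expect_error(latitude_ols(sm[1:2, ]), "at least 3")
  expect_error(latitude_ols(tibble::tibble(latitude = rep(30, 4),
                                           median_pql = 1:4)), "singular")
})

test_that("latitude regression matches the closed-form normal equations", {
  set.seed(17)
  sm <- tibble::tibble(latitude = medfly_sites()$latitude,
                       median_pql = 400 - 6 * medfly_sites()$latitude + rnorm(11, 0, 15))
  fit <- latitude_ols(sm)
  want <- oracle_ols(sm$latitude, sm$median_pql)
  expect_equal(fit$slope, want$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, want$intercept, tolerance = 1e-10)
  expect_equal(fit$F, want$F, tolerance = 1e-8)
  expect_equal(fit$p, want$p, tolerance = 1e-8)
  # invariant to site ordering
  perm <- sample(nrow(sm))
  fit2 <- latitude_ols(sm[perm, ])
  expect_equal(fit2$slope, fit$slope)
  expect_equal(fit2$F, fit$F)
})

test_that("nearest-site matching agrees with an exhaustive scan", {
  sites <- medfly_sites()
  at <- nearest_site(list(latitude = 36.780, longitude = -119.719), sites)
  expect_equal(at$callsign, "KFAT")
  set.seed(9)
  for (i in 1:100) {
    q <- list(latitude = runif(1, 32, 42), longitude = runif(1, -124, -114))
    d <- sapply(seq_len(nrow(sites)), function(j) {
      geosphere::distHaversine(c(q$longitude, q$latitude),
                               c(sites$longitude[j], sites$latitude[j]))
    })
    expect_equal(nearest_site(q, sites)$callsign, sites$callsign[which.min(d)])
  }
})

test_that("nearest-site ties break toward lower latitude then callsign", {
  sites <- tibble::tibble(callsign = c("KBBB", "KAAA"),
                          latitude = c(35, 33), longitude = c(-118, -118))
  mid <- list(latitude = 34, longitude = -118)
  expect_equal(nearest_site(mid, sites)$callsign, "KAAA")
  cosite <- tibble::tibble(callsign = c("KZZZ", "KAAA"),
                           latitude = c(34, 34), longitude = c(-118, -118))
  expect_equal(nearest_site(mid, cosite)$callsign, "KAAA")
})

test_that("degenerate paired comparisons behave as defined", {
  dates <- as.Date("2010-01-01") + 0:9
  norm <- compute_normals(tibble::tibble(date = dates, value = 1:10))
  x <- tibble::tibble(date = dates, value = c(5, 7, 3, 8, 2, 9, 4, 6, 1, 10))
  same <- paired_comparison(x, x, norm, norm)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- x
  shifted$value <- x$value - 3 + rnorm(10, 0, 0.1)
  cmp <- paired_comparison(x, shifted, norm, norm)
  expect_gt(cmp$t, 0)  # dd longer than abs: positive difference
})

test_that("the paired t equals the textbook formula", {
  set.seed(40)
  dates <- rep(as.Date("2010-01-01") + 0:16, 2)  # two values per calendar day
  dd <- tibble::tibble(date = dates, value = rnorm(34, 234, 79))
  ab <- tibble::tibble(date = dates, value = rnorm(34, 170, 22))
  ndd <- compute_normals(dd)
  nab <- compute_normals(ab)
  cmp <- paired_comparison(dd, ab, ndd, nab)
  d <- dd$value - ab$value
  t_book <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp$t, t_book, tolerance = 1e-10)
  expect_equal(cmp$df, 33)
})

test_that("known shift and variance ratio are recovered across replicates", {
  set.seed(59)
  reps <- 200
  n_days <- 17
  n <- 2 * n_days  # two years per calendar day
  delta <- 60
  sd_dd <- 24; sd_abs <- 8  # deviation variance ratio 9
  ts <- numeric(reps); fs <- numeric(reps)
  dates <- rep(as.Date("2010-06-01") + seq_len(n_days) - 1, 2)
  for (i in seq_len(reps)) {
    base <- rep(rnorm(n_days, 170, 5), 2)  # shared day-of-year level
    dd <- tibble::tibble(date = dates, value = base + delta + rnorm(n, 0, sd_dd))
    ab <- tibble::tibble(date = dates, value = base + rnorm(n, 0, sd_abs))
    cmp <- paired_comparison(dd, ab, compute_normals(dd), compute_normals(ab))
    ts[i] <- cmp$t
    fs[i] <- cmp$F
  }
  # the day-of-year level cancels in the paired differences, so the mean t is
  # the noncentrality times the mean of a t_(n-1) variate
  sd_diff <- sqrt(sd_dd^2 + sd_abs^2)
  ncp <- delta / (sd_diff / sqrt(n))
  df <- n - 1
  c_df <- sqrt(df / 2) * exp(lgamma((df - 1) / 2) - lgamma(df / 2))
  expect_lt(abs(mean(ts) - ncp * c_df), 3 * sd(ts) / sqrt(reps))
  # each two-value calendar day contributes one effective degree of freedom
  # to the deviation variances, so F ~ 9 * F(17, 17), mean 9 * 17/15
  expect_lt(abs(mean(fs) - 9 * n_days / (n_days - 2)), 3 * sd(fs) / sqrt(reps))
})
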