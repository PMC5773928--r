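test_that("gross outliers are removed and clean series pass untouched", {
  s <- constant_series(20, n_days = 3)[, c("timestamp", "temp_c")]
  spiked <- s
  spiked$temp_c[30] <- 55
  out <- remove_outliers(spiked, window_hours = 24, threshold_c = 10)
  expect_equal(nrow(out), nrow(s) - 1L)
  expect_false(55 %in% out$temp_c)
  expect_equal(remove_outliers(s, 24, 10), s)
})

test_that("fewer than 3 records are returned unchanged with a warning", {
  s <- constant_series(20, n_days = 1)[1:2, c("timestamp", "temp_c")]
  expect_warning(out <- remove_outliers(s), "fewer than 3")
  expect_identical(out, s)
})

test_that("all injected spikes in a synthetic year are removed with no false removals", {
  p <- synthetic_climate_params(defect_outlier_rate = 50, seed = 42)
  w <- generate_synthetic_weather(p, n_years = 1)
  spikes <- w$log[w$log$type == "outlier", ]
  expect_gt(nrow(spikes), 20)  # Poisson(50)
  cleaned <- remove_outliers(w$raw)
  # every spiked timestamp gone, every unspiked record kept
  expect_false(any(spikes$timestamp %in% cleaned$timestamp))
  keep_true <- w$raw[!w$raw$timestamp %in% spikes$timestamp, ]
  expect_equal(nrow(cleaned), nrow(keep_true))
  expect_equal(cleaned$temp_c, keep_true$temp_c)
})

test_that("small gaps fill by linear interpolation in time", {
  s <- constant_series(20, n_days = 3)[, c("timestamp", "temp_c")]
  s$temp_c[9] <- 10
  s$temp_c[11] <- 12
  s <- s[-10, ]  # one missing hour between 10 and 12
  out <- resample_and_fill(s)
  i <- 10
  expect_equal(out$temp_c[i], 11)
  expect_identical(out$fill_flag[i], "interpolated_small_gap")
})

test_that("large gaps fill day-over-day at the same hour", {
  s <- constant_series(20, n_days = 4)[, c("timestamp", "temp_c")]
  s$temp_c[15] <- 20          # day 1, 14:00
  s$temp_c[24 + 24 + 15] <- 24  # day 3, 14:00
  s <- s[-(26:55), ]          # 30 h gap: day 2 01:00 .. day 3 06:00
  out <- resample_and_fill(s)
  filled <- out[format(out$timestamp, "%Y-%m-%d %H") == "2010-01-02 14", ]
  expect_equal(filled$temp_c, 22)
  expect_identical(filled$fill_flag, "interpolated_day_over_day")
})

test_that("synthetic gap fills match an independent oracle, flags included", {
  p <- synthetic_climate_params(defect_gap_rate = 6, defect_gap_hours = 12, seed = 11)
  w <- generate_synthetic_weather(p, n_years = 1)
  expect_gt(sum(w$log$type == "gap"), 0)
  got <- resample_and_fill(w$raw)
  want <- oracle_fill(w$raw)
  expect_equal(got$temp_c, want$temp_c, tolerance = 1e-12)
  expect_identical(got$fill_flag, want$fill_flag)
})

test_that("resampling is idempotent and the identity on defect-free input", {
  p <- quiet_climate(seed = 3)
  w <- generate_synthetic_weather(p, n_years = 1)
  once <- resample_and_fill(w$clean)
  expect_equal(once$temp_c, w$clean$temp_c)
  expect_true(all(once$fill_flag == "observed"))
  p2 <- synthetic_climate_params(defect_gap_rate = 4, seed = 8)
  w2 <- generate_synthetic_weather(p2, n_years = 1)
  once2 <- resample_and_fill(w2$raw)
  twice2 <- resample_and_fill(once2)
  expect_equal(twice2$temp_c, once2$temp_c)
  expect_identical(twice2$fill_flag, once2$fill_flag)
  # observed count equals retained on-the-hour raw observations
  expect_equal(sum(once2$fill_flag == "observed"), nrow(w2$raw))
})

test_that("boundary gaps are an error, not an extrapolation", {
  s <- constant_series(20, n_days = 3)[, c("timestamp", "temp_c")]
  s <- s[-(2:10), ]  # gap touching the start: no earlier day to bracket
  expect_error(resample_and_fill(s), "unfillable")
})

test_that("daily extremes cover complete days only", {
  s <- constant_series(15, n_days = 1)
  expect_equal(daily_extremes(s)[, c("tmin", "tmax")],
               tibble::tibble(tmin = 15, tmax = 15))
  s2 <- constant_series(0, n_days = 1)
  s2$temp_c <- 0:23
  ext2 <- daily_extremes(s2)
  expect_equal(c(ext2$tmin, ext2$tmax), c(0, 23))
  # partial boundary days excluded
  s3 <- constant_series(10, n_days = 3)[5:60, ]
  ext3 <- daily_extremes(s3)
  expect_equal(nrow(ext3), 1L)
  expect_equal(ext3$date, as.Date("2010-01-02"))
})

test_that("a sinusoidal day recovers its extremes up to hourly discretisation", {
  p <- quiet_climate(annual_amplitude = 0, annual_mean = 20, diurnal_amplitude = 5)
  w <- generate_synthetic_weather(p, n_years = 1)
  ext <- daily_extremes(w$clean)
  expect_true(all(abs(ext$tmin - 15) < 0.2))
  expect_true(all(abs(ext$tmax - 25) < 0.2))
})
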