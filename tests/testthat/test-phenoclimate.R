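# Thermal-season segmentation and growing-season covariates.

# brute-force scan oracle: first day of the earliest run of >= N days
# satisfying cond, at/after `from`
.oracle_first_run <- function(cond, N, from = 1) {
  for (i in from:(length(cond) - N + 1))
    if (all(cond[i:(i + N - 1)])) return(i)
  NA_integer_
}

test_that("piecewise-constant year recovers planted season starts", {
  w <- step_weather_year()
  for (N in c(1, 5, 30, 60)) {
    seg <- segment_thermal_seasons(w, N = N)
    expect_equal(seg$spring, 91)
    expect_equal(seg$summer, 151)
    expect_equal(seg$autumn, 241)
    expect_equal(seg$winter, 301)
  }
  seg <- segment_thermal_seasons(w, N = 5)
  expect_true(all(!is.na(seg$season)))
  expect_equal(as.character(seg$season[90]), "winter")
  expect_equal(as.character(seg$season[155]), "summer")
})

test_that("degenerate series: conditions never met or runs too short", {
  n <- 365
  frozen <- daily_weather(seq(as.Date("2015-01-01"), by = "day",
                              length.out = n), rep(-5, n))
  seg <- segment_thermal_seasons(frozen, N = 5)
  expect_true(is.na(seg$spring))
  expect_true(is.na(seg$summer))
  expect_true(is.na(seg$autumn))

  # one warm day inside winter with N = 5: no spring
  t <- rep(-5, n); t[40] <- 3
  warm1 <- daily_weather(seq(as.Date("2015-01-01"), by = "day",
                             length.out = n), t)
  expect_true(is.na(segment_thermal_seasons(warm1, N = 5)$spring))
  expect_equal(segment_thermal_seasons(warm1, N = 1)$spring, 40)
})

test_that("with N = 1 segmentation reduces to first-crossing detection", {
  set.seed(11)
  for (i in 1:20) {
    t <- stats::arima.sim(list(ar = 0.8), 365, sd = 4) +
      4 - 13 * cos(2 * pi * (1:365 - 15) / 365)
    w <- daily_weather(seq(as.Date("2015-01-01"), by = "day",
                           length.out = 365), as.numeric(t))
    seg <- segment_thermal_seasons(w, N = 1)
    expect_equal(seg$spring, .oracle_first_run(w$t_mean > 0, 1))
    if (!is.na(seg$spring))
      expect_equal(seg$summer,
                   .oracle_first_run(w$t_mean > 10, 1, from = seg$spring))
  }
})

test_that("segmentation shifts with prepended frozen days, otherwise stable", {
  w <- step_weather_year()
  seg <- segment_thermal_seasons(w, N = 5)
  k <- 30
  t2 <- c(rep(-5, k), w$t_mean)
  w2 <- daily_weather(seq(as.Date("2014-12-02"), by = "day",
                          length.out = length(t2)), t2)
  seg2 <- segment_thermal_seasons(w2, N = 5)
  expect_equal(seg2$spring, seg$spring + k)
  expect_equal(seg2$summer, seg$summer + k)
  expect_equal(seg2$autumn, seg$autumn + k)
  expect_equal(seg2$winter, seg$winter + k)
})

test_that("effective temperature sum and day counters", {
  w <- step_weather_year()
  seg <- segment_thermal_seasons(w, N = 5)
  # hand summation: growing season starts day 151 (first t_mean > 5);
  # days 151-160 contribute 10 x (15 - 5) = 100 degree-days
  gv <- growing_season_variables(w, seg, 160, T_base = 5)
  expect_equal(gv$effective_temperature_sum, 100)
  expect_equal(gv$days_from_growing_season_start, 9)
  # at the start day itself the sum is one day's excess
  gv0 <- growing_season_variables(w, seg, 151, T_base = 5)
  expect_equal(gv0$effective_temperature_sum, 10)
  # before the growing season: sum 0, counter undefined
  gv_pre <- growing_season_variables(w, seg, 120, T_base = 5)
  expect_equal(gv_pre$effective_temperature_sum, 0)
  expect_true(is.na(gv_pre$days_from_growing_season_start))
  # sum is non-decreasing in DOY
  sums <- vapply(100:300, function(d)
    growing_season_variables(w, seg, d)$effective_temperature_sum,
    numeric(1))
  expect_true(all(diff(sums) >= 0))
  # snowmelt on day 100 (first of >= K snow-free days)
  gv_snow <- growing_season_variables(w, seg, 110, K = 7)
  expect_equal(gv_snow$days_post_snowmelt, 10)
  expect_error(growing_season_variables(w, seg, 9999), "outside series")
})

test_that("temperature sum at the base temperature accumulates nothing", {
  n <- 365
  t <- rep(5, n)
  w <- daily_weather(seq(as.Date("2015-01-01"), by = "day",
                         length.out = n), t)
  seg <- segment_thermal_seasons(w, N = 5)
  # t_mean never strictly above T_base: no growing season, sum 0
  gv <- growing_season_variables(w, seg, 180, T_base = 5)
  expect_equal(gv$effective_temperature_sum, 0)
})

test_that("weather-covariate correlations: exact, null and degenerate", {
  cov <- data.frame(doy = 1:20, days_from_growing_season_start = 0:19)
  iflav <- data.frame(doy = 1:20, iflav = 3 - 0.05 * (0:19))
  res <- correlate_weather_iflav(iflav, cov)
  expect_equal(res$r, -1, tolerance = 1e-12)

  set.seed(3)
  covn <- data.frame(doy = 1:1000, x = stats::rnorm(1000))
  ifn <- data.frame(doy = 1:1000, iflav = stats::rnorm(1000))
  expect_lt(abs(correlate_weather_iflav(ifn, covn)$r), 0.1)

  const <- data.frame(doy = 1:20, iflav = rep(2, 20))
  expect_true(is.na(correlate_weather_iflav(const, cov)$r))
})
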