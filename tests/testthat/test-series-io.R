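test_that("gappy year labels are densified to explicit missing values", {
  s <- annual_series(c(1950, 1952), c(1.5, 2.5))
  expect_identical(s$years, 1950:1952)
  expect_equal(s$values, c(1.5, NA, 2.5))

  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,value", "1950,1.5", "1952,2.5"), p)
  r <- read_series(p)
  expect_identical(r$years, 1950:1952)
  expect_equal(r$values, c(1.5, NA, 2.5))
})

test_that("write/read round-trips years, values and missingness", {
  sc <- make_scenario(scenario_config(seed = 4))
  s <- sc$series$FSC           # has leading missing years from the lag
  p <- withr::local_tempfile(fileext = ".csv")
  write_series(s, p)
  r <- read_series(p, name = s$name)
  expect_identical(r$years, s$years)
  expect_equal(r$values, s$values, tolerance = 1e-12)
  expect_identical(r$name, s$name)
})

test_that("format errors name the offending year or line", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,value", "1959,1", "1960,2", "1960,3"), p)
  expect_error(read_series(p), "1960")

  writeLines(c("year,value", "1959,1", "abc,2"), p)
  expect_error(read_series(p), "line 2")

  expect_error(annual_series(c(1950, 1950, 1951), 1:3), "1950")
})

test_that("anomalies subtract the baseline mean over non-missing years", {
  const <- toy_series(rep(3.7, 20))
  expect_equal(to_anomalies(const, 1950, 1969)$values, rep(0, 20))

  s <- toy_series(rnorm(40), units = "degC")
  a <- to_anomalies(s, NULL, NULL)   # full-span baseline
  expect_lt(abs(mean(a$values)), 1e-12)
  expect_identical(a$units, "degC")

  # step series: baseline mean inside the window, +1 outside
  step <- toy_series(c(rep(2, 15), rep(3, 10)))
  a2 <- to_anomalies(step, 1950, 1964)
  expect_equal(a2$values, c(rep(0, 15), rep(1, 10)))

  expect_error(to_anomalies(toy_series(rnorm(20)), 1800, 1805), "baseline")
})

test_that("linear detrending removes exactly linear structure and is idempotent", {
  lin <- toy_series(5 + 0.25 * (1950:2009 - 1950))
  expect_lt(max(abs(detrend_linear(lin)$values)), 1e-10)

  s <- simulate_upstream_index(60, 0.5, 1, seed = 9)
  s$values <- s$values + 0.05 * (s$years - s$years[1])
  d <- detrend_linear(s)
  # refit oracle: residual slope must vanish
  refit <- stats::lm(d$values ~ d$years)
  expect_lt(abs(coef(refit)[2]), 1e-10)
  expect_equal(detrend_linear(d)$values, d$values, tolerance = 1e-10)
})

test_that("high-pass and low-pass are exactly complementary", {
  expect_lt(max(abs(highpass(toy_series(rep(2, 30)))$values)), 1e-14)

  s <- simulate_upstream_index(80, 0.4, 1, seed = 2)
  s$values[10] <- NA
  hp <- highpass(s, 5)
  lp <- lowpass(s, 5)
  both <- !is.na(s$values)
  expect_equal(hp$values[both] + lp$values[both], s$values[both],
               tolerance = 1e-12)
  expect_true(is.na(hp$values[10]))

  # 2-year oscillation: a 5-point boxcar has gain 1/5 at the Nyquist
  # frequency, so the high-pass retains (1 - 1/5)^2 = 64% of the variance
  osc <- toy_series(cos(pi * seq_len(60)))
  hp2 <- highpass(osc, 5)
  interior <- 3:58
  expect_equal(var(hp2$values[interior]) / var(osc$values[interior]), 0.64,
               tolerance = 1e-10)

  expect_error(highpass(s, 1), "cutoff")
})

test_that("anomaly and detrend transforms commute on gap-free series", {
  s <- simulate_upstream_index(60, 0.5, 1, seed = 17)
  s$values <- s$values + 0.03 * (s$years - 1980) + 2
  a <- detrend_linear(to_anomalies(s, NULL, NULL))
  b <- to_anomalies(detrend_linear(s), NULL, NULL)
  expect_equal(a$values, b$values, tolerance = 1e-10)
})

test_that("harvest rate is catch/TSB on the year intersection", {
  tsb <- toy_series(seq(1000, 2900, by = 100), name = "TSB")
  catch <- toy_series(0.3 * seq(1000, 2900, by = 100), name = "catch")
  hr <- harvest_rate(catch, tsb)
  expect_equal(hr$values, rep(0.3, 20))

  catch2 <- annual_series(1955:1964, rep(700, 10), name = "catch")
  tsb2 <- annual_series(1950:1969, rep(2000, 20), name = "TSB")
  hr2 <- harvest_rate(catch2, tsb2)
  expect_identical(range(hr2$years), c(1955L, 1964L))
  expect_equal(hr2$values, rep(0.35, 10))

  tsb_bad <- toy_series(c(rep(1000, 10), 0, rep(1000, 9)), name = "TSB")
  expect_error(harvest_rate(catch, tsb_bad), "non-positive")
})

test_that("alignment keeps exactly the complete lagged rows", {
  set.seed(1)
  y <- annual_series(1950:2012, rnorm(63), "TSB")
  x <- annual_series(1950:2012, rnorm(63), "AMO")
  d <- align(y, list(AMO = x), 7)
  expect_identical(d$years, 1957:2012)   # 56 rows by enumeration
  expect_equal(nrow(d$X), 56L)
  expect_equal(d$X[, "AMO"], value_at(x, d$years - 7))

  d0 <- align(y, list(TSB = y), 0)
  expect_equal(d0$X[, "TSB"], d0$y)

  x2 <- x
  x2$values[x2$years == 1970] <- NA
  d2 <- align(y, list(AMO = x2), 7)
  expect_false(1977L %in% d2$years)
  expect_true(1976L %in% d2$years)
})

test_that("alignment is invariant to predictor order", {
  set.seed(2)
  y <- annual_series(1950:2012, rnorm(63), "TSB")
  a <- annual_series(1950:2012, rnorm(63), "A")
  b <- annual_series(1950:2010, rnorm(61), "B")
  d1 <- align(y, list(A = a, B = b), c(7, 3))
  d2 <- align(y, list(B = b, A = a), c(3, 7))
  expect_identical(d1$years, d2$years)
  expect_equal(d1$X[, c("A", "B")], d2$X[, c("A", "B")])
})

test_that("impossible alignment reports per-series coverage", {
  y <- annual_series(1950:1970, rnorm(21), "y")
  x <- annual_series(2000:2020, rnorm(21), "x")
  expect_error(align(y, list(x = x), 2), "coverage|1950-1970|2000-2020")
})
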