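test_that("upstream AR(1) index has the configured memory and scale", {
  # determinism under a fixed seed
  a <- simulate_upstream_index(60, 0.7, 1, seed = 5)
  b <- simulate_upstream_index(60, 0.7, 1, seed = 5)
  expect_identical(a$values, b$values)

  # white-noise limit
  w <- simulate_upstream_index(5000, 0, 1, seed = 6)
  ac1 <- cor(w$values[-1], w$values[-5000])
  expect_lt(abs(ac1), 0.05)

  # closed-form lag-1 autocorrelation and marginal SD at long n
  s <- simulate_upstream_index(5000, 0.7, 1.5, seed = 7)
  expect_lt(abs(cor(s$values[-1], s$values[-5000]) - 0.7), 0.03)
  expect_lt(abs(sd(s$values) / 1.5 - 1), 0.05)
  expect_lt(abs(mean(s$values)), 0.1)

  expect_error(simulate_upstream_index(60, 1.0, 1, seed = 1), "stationar")
})

test_that("anomaly propagation shifts, attenuates and masks the start", {
  src <- simulate_upstream_index(40, 0.5, 1, seed = 3, name = "up")
  tg <- propagate_anomaly(src, 3, 1, 0, seed = 4, name = "down")
  expect_identical(tg$years, src$years)
  expect_true(all(is.na(tg$values[1:3])))
  expect_equal(tg$values[4:40], src$values[1:37])

  expect_error(propagate_anomaly(toy_series(c(1, 2)), 3, 1, 0), "too short")
})

test_that("signal-plus-noise link correlation matches the closed form", {
  src <- simulate_upstream_index(5000, 0.7, 1, seed = 11)
  tg <- propagate_anomaly(src, 3, 0.8, 0.6, seed = 12)
  # theoretical peak correlation 0.8/sqrt(0.64+0.36) = 0.8 at lag 3
  prof <- lagged_correlation(src, tg, 0, 6, detrend = FALSE)
  pk <- peak_lag(prof)
  expect_identical(pk$lag, 3L)
  expect_lt(abs(pk$r - 0.8), 0.05)
})

test_that("a chain of lags 3 then 4 peaks end-to-end at lag 7", {
  src <- simulate_upstream_index(2000, 0.6, 1, seed = 21)
  mid <- propagate_anomaly(src, 3, 0.9, 0.3, seed = 22)
  end <- propagate_anomaly(mid, 4, 0.9, 0.3, seed = 23)
  pk <- peak_lag(lagged_correlation(src, end, 0, 10, detrend = FALSE))
  expect_identical(pk$lag, 7L)
})

test_that("stock equation reproduces its analytic R-squared", {
  d <- recovery_design(1, n_years = 5000L)$design
  fit <- summary(lm(d$y ~ d$X))
  expect_lt(abs(fit$r.squared - 0.61), 0.05)

  # noiseless single-driver limit: exact lagged copy
  drv <- simulate_upstream_index(50, 0.5, 1, seed = 31, name = "d")
  st <- simulate_stock(list(d = drv), 7, 1, noise_sd = 0, name = "s")
  expect_equal(value_at(st, st$years[10:50]),
               value_at(drv, st$years[10:50] - 7))

  expect_error(simulate_stock(list(d = drv), c(1, 2), 1, noise_sd = 0),
               "equal length")
})

test_that("a negative lagged harvest effect induces a negative lagged correlation", {
  h <- simulate_upstream_index(3000, 0.5, 1, seed = 41, name = "H")
  drv <- simulate_upstream_index(3000, 0.6, 1, seed = 42, name = "d")
  st <- simulate_stock(list(d = drv), 4, 0.6, harvest = h,
                       harvest_coeff = -0.4, harvest_lag = 2,
                       noise_sd = 0.5, seed = 43)
  prof <- lagged_correlation(h, st, 0, 5, detrend = FALSE)
  pk <- peak_lag(prof)
  expect_identical(pk$lag, 2L)
  expect_lt(pk$r, 0)
})

test_that("scenario realization is deterministic and calendar-consistent", {
  s1 <- make_scenario(scenario_config(seed = 8))
  s2 <- make_scenario(scenario_config(seed = 8))
  for (nm in names(s1$series)) {
    expect_identical(s1$series[[nm]]$values, s2$series[[nm]]$values)
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(s1, d1)
  write_scenario(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("scenario ground truth matches configured lags and long-run estimates", {
  tr <- make_scenario(scenario_config(seed = 1))$truth
  expect_equal(tr$links$peak_lag, tr$links$configured_lag)
  expect_true(all(abs(tr$links$peak_r) <= 1))
  expect_true(all(abs(tr$upstream_to$peak_r) <= 1))

  # brute-force check of the closed forms on a long realization
  big <- make_scenario(scenario_config(n_years = 5000, seed = 2))
  for (i in seq_len(nrow(tr$links))) {
    emp <- oracle_lag_cor(big$series[[tr$links$source[i]]],
                          big$series[[tr$links$target[i]]],
                          tr$links$configured_lag[i])
    expect_lt(abs(emp - tr$links$peak_r[i]), 0.05)
  }
  st <- big$config$stock
  emp_up <- oracle_lag_cor(big$series$AMO, big$series$TSB, 7)
  theo_up <- tr$upstream_to$peak_r[tr$upstream_to$target == "TSB"]
  expect_lt(abs(emp_up - theo_up), 0.05)

  # theoretical multiple correlation vs long-sample OLS at the true lags
  d <- align(big$series$TSB, big$series[st$drivers], st$lags)
  r2 <- summary(lm(d$y ~ d$X))$r.squared
  expect_lt(abs(sqrt(r2) - theoretical_multiple_r(tr)), 0.02)
})

test_that("noiseless unit-gain scenario degenerates to exact lagged copies", {
  cfg <- scenario_config(
    upstream = list(name = "AMO", ar1 = 0.6, sd = 1),
    chain = list(list(source = "AMO", target = "FSC", lag_years = 3,
                      gain = 1, noise_sd = 0),
                 list(source = "FSC", target = "BSO", lag_years = 1,
                      gain = 1, noise_sd = 0)),
    stock = list(name = "TSB", drivers = "BSO", lags = 3L, coeffs = 1,
                 harvest_coeff = 0, harvest_lag = 2L, noise_sd = 0),
    recruitment = list(name = "REC3", lead = 2L, gain = 1, noise_sd = 0),
    seed = 3)
  sc <- make_scenario(cfg)
  amo <- sc$series$AMO
  yrs <- sc$series$TSB$years[-(1:7)]
  expect_equal(value_at(sc$series$TSB, yrs), value_at(amo, yrs - 7))
  expect_equal(value_at(sc$series$FSC, yrs), value_at(amo, yrs - 3))
  expect_equal(sc$truth$rho_drivers, 1)
})

test_that("invalid scenario configurations are rejected", {
  expect_error(scenario_config(n_years = 20), ">= 30")
  expect_error(scenario_config(chain = list(
    list(source = "FSC", target = "BSO", lag_years = 1, gain = 1,
         noise_sd = 0.1))), "not yet defined")
  expect_error(scenario_config(chain = list(
    list(source = "AMO", target = "AMO", lag_years = 1, gain = 1,
         noise_sd = 0.1))), "cyclic")
  expect_error(scenario_config(stock = list(name = "TSB", drivers = "FSC",
                                            lags = 40L, coeffs = 1,
                                            harvest_coeff = 0,
                                            harvest_lag = 0L,
                                            noise_sd = 0.5)),
               "n_years/2")
})
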