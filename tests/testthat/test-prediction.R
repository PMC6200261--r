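test_that("noiseless linear data are fit exactly", {
  x <- simulate_upstream_index(40, 0.3, 1, seed = 1, name = "x")
  y <- annual_series(x$years, 2 + 0.5 * x$values, "y")
  m <- fit_model(align(y, list(x = x), 0))
  expect_equal(unname(m$coefficients), c(2, 0.5), tolerance = 1e-10)
  expect_lt(m$sigma, 1e-10)
})

test_that("coefficients match a brute-force normal-equations solve", {
  set.seed(42)
  y <- annual_series(1961:2000, rnorm(40), "y")
  x1 <- annual_series(1961:2000, rnorm(40), "a")
  x2 <- annual_series(1961:2000, rnorm(40), "b")
  d <- align(y, list(a = x1, b = x2), 0)
  m <- fit_model(d)
  X <- cbind(1, d$X)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% d$y)   # explicit normal equations
  expect_equal(unname(m$coefficients), unname(drop(beta_oracle)),
               tolerance = 1e-8)
  # residual SD with the n - p - 1 denominator
  e <- d$y - drop(X %*% beta_oracle)
  expect_equal(m$sigma, sqrt(sum(e^2) / (40 - 3)), tolerance = 1e-10)
})

test_that("residuals are centered and training predictions reproduce fitted values", {
  d <- recovery_design(3)$design
  m <- fit_model(d)
  expect_lt(abs(mean(m$residuals)), 1e-10)
  rd <- recovery_design(3)
  fc <- retro_forecast(m, list(X1 = rd$x1, X2 = rd$x2))
  idx <- match(m$years, fc$year)
  expect_equal(fc$fit[idx], m$fitted, tolerance = 1e-12)
})

test_that("rank deficiency is an actionable error", {
  set.seed(7)
  y <- annual_series(1961:2000, rnorm(40), "y")
  x <- annual_series(1961:2000, rnorm(40), "a")
  dup <- annual_series(x$years, x$values, "b")
  d <- align(y, list(a = x, b = dup), 0)
  expect_error(fit_model(d), "orthogonalize")
})

test_that("successive residualization decorrelates columns without changing the fit", {
  d <- recovery_design(5)$design
  # make the predictors strongly collinear
  d$X[, 2] <- 0.9 * d$X[, 1] + 0.1 * d$X[, 2]
  od <- orthogonalize_predictors(d)
  expect_lt(abs(cor(od$X[, 1], od$X[, 2])), 1e-10)

  m_raw <- fit_model(d)
  m_ortho <- fit_model(od)
  expect_true(m_ortho$orthogonalized)
  # span invariance: same fitted values, different coefficients
  expect_equal(m_ortho$fitted, m_raw$fitted, tolerance = 1e-8)
  expect_equal(m_ortho$residuals, m_raw$residuals, tolerance = 1e-8)

  # idempotence on already-orthogonal columns
  od2 <- orthogonalize_predictors(od)
  expect_equal(od2$X, od$X, tolerance = 1e-10)

  # duplicated column collapses to a degenerate zero residual
  d$X[, 2] <- d$X[, 1]
  dd <- orthogonalize_predictors(d)
  expect_lt(max(abs(dd$X[, 2])), 1e-10)
  expect_identical(attr(dd, "degenerate"), colnames(d$X)[2])
})

test_that("Durbin-Watson follows 2(1 - rho1) and matches lmtest", {
  ar_resid <- function(rho, n, seed) {
    with(list(), {
      set.seed(seed)
      e <- numeric(n)
      e[1] <- rnorm(1)
      for (t in 2:n) e[t] <- rho * e[t - 1] + rnorm(1, sd = sqrt(1 - rho^2))
      e
    })
  }
  expect_lt(abs(durbin_watson(ar_resid(0, 5000, 1))$dw - 2), 0.1)
  expect_lt(abs(durbin_watson(ar_resid(0.4, 5000, 2))$dw - 1.2), 0.1)

  # independent implementation cross-check on a real regression fit
  set.seed(3)
  df <- data.frame(x = rnorm(50))
  df$y <- 1 + 2 * df$x + rnorm(50)
  fit <- lm(y ~ x, data = df)
  expect_equal(durbin_watson(residuals(fit))$dw,
               unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-10)

  # gaps restrict differencing to consecutive runs
  gw <- durbin_watson(rnorm(30), years = c(1950:1964, 1970:1984))
  expect_true(gw$gaps)
})

test_that("diagnostics flag autocorrelated residuals but pass clean ones", {
  d <- recovery_design(11)$design
  m <- fit_model(d)
  rep <- diagnose(m)
  expect_gte(rep$dw, 0)
  expect_lte(rep$dw, 4)
  expect_true(rep$flags[["normal"]])

  # plant AR(1) rho ~ 0.6 structure in the predictand noise
  set.seed(9)
  n <- length(d$y)
  ar <- as.numeric(arima.sim(list(ar = 0.6), n, sd = 0.8))
  d2 <- d
  d2$y <- drop(cbind(1, d2$X) %*% c(0, 0.6, 0.5)) + ar
  rep2 <- diagnose(fit_model(d2))
  expect_gt(rep2$resid_ac1, 0.2)
  expect_false(rep2$flags[["independent"]])
})

test_that("prediction intervals track a parametric-bootstrap oracle", {
  rd <- recovery_design(13, n_years = 60)
  m <- fit_model(rd$design)
  fc <- suppressMessages(
    predict(m, list(X1 = rd$x1, X2 = rd$x2), years = c(2000L, 2015L)))
  V <- m$xtx_inv
  set.seed(99)
  n_draw <- 10000
  for (i in seq_len(nrow(fc))) {
    x0 <- c(1, value_at(rd$x1, fc$year[i] - 7), value_at(rd$x2, fc$year[i] - 7))
    # draw sigma* from its chi-square posterior, beta* | sigma*, then y*
    sig2 <- m$sigma^2 * m$df / rchisq(n_draw, m$df)
    L <- chol(V)
    beta_draw <- matrix(rnorm(3 * n_draw), n_draw) %*% L * sqrt(sig2)
    y_star <- drop(beta_draw %*% x0) + rnorm(n_draw, sd = sqrt(sig2)) +
      sum(x0 * m$coefficients)
    half_boot <- diff(quantile(y_star, c(0.025, 0.975), names = FALSE)) / 2
    half_model <- (fc$upr[i] - fc$lwr[i]) / 2
    expect_lt(abs(half_model / half_boot - 1), 0.1)
  }
})

test_that("a near-perfect fit leaves only parameter uncertainty in the interval", {
  x <- simulate_upstream_index(200, 0.3, 1, seed = 21, name = "x")
  y <- annual_series(x$years, 1 + 0.4 * x$values, "y")
  m <- fit_model(align(y, list(x = x), 0))
  fc_par <- predict(m, list(x = x), years = x$years[100], interval = "parameter")
  expect_lt(fc_par$upr - fc_par$lwr, 1e-8)
})

test_that("forecasts extend exactly lead years beyond the data", {
  # predictors observed through 2017 with lead 7 support forecasts to 2024
  x <- annual_series(1950:2017, rnorm(68), "x")
  y <- annual_series(1950:2010, rnorm(61), "y")
  m <- fit_model(align(y, list(x = x), 7))
  fc <- suppressMessages(predict(m, list(x = x)))
  expect_identical(max(fc$year), 2024L)
  expect_true(all(fc$future[fc$year > 2010]))
  expect_false(any(fc$future[fc$year <= 2010]))
})

test_that("persistence forecasts are exact lagged copies of the observations", {
  obs <- simulate_upstream_index(50, 0.5, 1, seed = 31, name = "obs")
  for (l in 1:7) {
    pf <- persistence_forecast(obs, l)
    # element-wise brute-force construction
    expect_equal(pf$fit, value_at(obs, pf$year - l))
    expect_identical(sum(pf$future), l)
  }
  expect_error(persistence_forecast(obs, 0), ">= 1")
})

test_that("random-chance models permute predictors and nothing else", {
  d <- recovery_design(17)$design
  set.seed(1)
  sh <- codcast:::shuffle_design(d)
  for (k in 1:2) {
    expect_identical(sort(sh$X[, k]), sort(d$X[, k]))
  }
  expect_identical(sh$y, d$y)
  m <- random_chance_model(d, seed = 2)
  expect_s3_class(m, "lag_lm")
  expect_lt(abs(cor(m$fitted, d$y)), 0.5)
})

test_that("OLS beats randomly perturbed coefficient vectors on training MSE", {
  d <- recovery_design(19)$design
  m <- fit_model(d)
  X <- cbind(1, d$X)
  mse <- mean((d$y - drop(X %*% m$coefficients))^2)
  set.seed(5)
  for (i in 1:25) {
    pert <- m$coefficients + rnorm(3, sd = 0.05)
    expect_gte(mean((d$y - drop(X %*% pert))^2), mse)
  }
})

test_that("fitting on every second year yields virtually the same coefficients", {
  # halving the sample removes the lag-1 autocorrelation of the record; the
  # regression coefficients must be robust to it
  for (seed in c(23, 24, 25)) {
    d <- recovery_design(seed)$design
    m_full <- fit_model(d)
    odd <- seq(1, length(d$y), by = 2)
    m_half <- fit_model(codcast:::design_rows(d, odd))
    se_full <- m_full$sigma * sqrt(diag(m_full$xtx_inv))
    for (k in 2:3) {
      expect_lt(abs(m_half$coefficients[k] - m_full$coefficients[k]),
                3 * se_full[k] * sqrt(2))
    }
  }
})
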