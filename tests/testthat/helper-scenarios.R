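# Shared fixtures, all generated in code.

# Short deterministic series for I/O and preprocessing tests.
toy_series <- function(values, start = 1950L, name = "toy", units = "") {
  annual_series(seq.int(start, length.out = length(values)), values,
                name = name, units = units)
}

# Two independent standardized AR(1) drivers, stock with known coefficients
# (0.6, 0.5) and noise chosen so the population R^2 is 0.61
# (rho = sqrt(0.61) ~ 0.781). Returns the aligned lead-l design.
recovery_design <- function(seed, n_years = 60L, lead = 7L) {
  x1 <- simulate_upstream_index(n_years, 0.3, 1, seed = 3L * seed + 11L,
                                name = "X1")
  x2 <- simulate_upstream_index(n_years, 0.3, 1, seed = 3L * seed + 12L,
                                name = "X2")
  y <- simulate_stock(list(X1 = x1, X2 = x2), c(lead, lead), c(0.6, 0.5),
                      noise_sd = sqrt(0.39), seed = 3L * seed + 13L,
                      name = "Y")
  list(x1 = x1, x2 = x2, y = y,
       design = align(y, list(X1 = x1, X2 = x2), lead))
}

# Retrospective forecast of a fitted model over its predictable past years.
retro_forecast <- function(model, series) {
  fc <- suppressMessages(stats::predict(model, series))
  out <- fc[!fc$future, , drop = FALSE]
  class(out) <- class(fc)
  attr(out, "provenance") <- attr(fc, "provenance")
  out
}

# Brute-force lagged Pearson correlation oracle: explicit shift of plain
# vectors, optional per-segment detrending via lm().
oracle_lag_cor <- function(x, y, l, detrend = FALSE) {
  yrs <- y$years
  xv <- rep(NA_real_, length(yrs))
  src <- match(yrs - l, x$years)
  ok0 <- !is.na(src)
  xv[ok0] <- x$values[src[ok0]]
  keep <- !is.na(xv) & !is.na(y$values)
  xs <- xv[keep]
  ys <- y$values[keep]
  yr <- yrs[keep]
  if (detrend) {
    xs <- stats::residuals(stats::lm(xs ~ yr))
    ys <- stats::residuals(stats::lm(ys ~ yr))
  }
  stats::cor(xs, ys)
}
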