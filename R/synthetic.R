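#' Simulate a red-noise upstream climate index
#'
#' Stationary AR(1) process `x_t = a x_{t-1} + innov_t` with innovations
#' scaled so the marginal standard deviation equals `sd`. A 100-step burn-in
#' removes the initialization transient before `n_years` values are kept.
#' Emulates a basin-scale SST index (AMO/SPG-like) whose redness carries the
#' multi-year memory that the downstream advective chain propagates.
#'
#' @param n_years number of calendar years to return.
#' @param ar1_coeff lag-1 autocorrelation `a`, in `[0, 1)`.
#' @param sd marginal standard deviation (> 0).
#' @param seed integer seed (or `NULL` to use the current RNG stream).
#' @param start_year first calendar year label.
#' @param name series name.
#' @return an [annual_series].
#' @export
simulate_upstream_index <- function(n_years, ar1_coeff, sd = 1, seed = NULL,
                                    start_year = 1958L, name = "AMO") {
  if (ar1_coeff >= 1 || ar1_coeff < 0) {
    stopf("ar1_coeff must be in [0, 1) for a stationary AR(1); got %g",
          ar1_coeff)
  }
  if (sd <= 0) stopf("sd must be positive")
  burn <- 100L
  n <- as.integer(n_years)
  with_seed(seed, {
    innov_sd <- sd * sqrt(1 - ar1_coeff^2)
    e <- stats::rnorm(burn + n, sd = innov_sd)
    x <- numeric(burn + n)
    x[1L] <- stats::rnorm(1L, sd = sd)
    for (t in 2L:(burn + n)) x[t] <- ar1_coeff * x[t - 1L] + e[t]
    annual_series(seq.int(start_year, length.out = n), x[(burn + 1L):(burn + n)],
                  name = name)
  })
}

#' Propagate an anomaly downstream with lag, attenuation and noise
#'
#' `target_t = gain * source_{t-lag} + noise_t`, mimicking the multi-year
#' advective travel of hydrographic anomalies between ocean sections. The
#' first `lag_years` target years (which have no upstream value - there is
#' no wrap-around) are explicitly missing; calendar labelling is identical
#' to the source.
#'
#' @param source an [annual_series].
#' @param lag_years non-negative integer travel time.
#' @param gain multiplicative attenuation/amplification.
#' @param noise_sd standard deviation of additive white noise (>= 0).
#' @param seed integer seed or `NULL`.
#' @param name target series name.
#' @return an [annual_series] on the source's years.
#' @export
propagate_anomaly <- function(source, lag_years, gain, noise_sd, seed = NULL,
                              name = paste0(source$name, "_lagged")) {
  stopifnot(inherits(source, "annual_series"))
  lag_years <- as.integer(lag_years)
  if (lag_years < 0L) stopf("lag_years must be non-negative")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  n <- length(source$years)
  if (n < lag_years + 2L) {
    stopf("source '%s' too short (%d years) for lag %d", source$name, n,
          lag_years)
  }
  with_seed(seed, {
    noise <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else numeric(n)
    v <- rep(NA_real_, n)
    idx <- (lag_years + 1L):n
    v[idx] <- gain * source$values[idx - lag_years] + noise[idx]
    annual_series(source$years, v, name = name, units = source$units)
  })
}

#' Simulate a stock biomass series from lagged drivers and harvest pressure
#'
#' `stock_t = sum_n coeff_n * driver_{t-lag_n, n} +
#'  harvest_coeff * harvest_{t-harvest_lag} + noise_t`.
#' Years for which any lagged input is unavailable are missing.
#'
#' @param drivers named list of [annual_series] hydrographic drivers.
#' @param lags non-negative integer lag per driver.
#' @param coeffs coefficient per driver.
#' @param harvest optional harvest-rate [annual_series].
#' @param harvest_coeff coefficient on the lagged harvest rate (negative for
#'   a depressing effect of fishing pressure).
#' @param harvest_lag non-negative integer lag of the harvest effect.
#' @param noise_sd standard deviation of additive white noise.
#' @param seed integer seed or `NULL`.
#' @param name series name.
#' @return an [annual_series].
#' @export
simulate_stock <- function(drivers, lags, coeffs, harvest = NULL,
                           harvest_coeff = 0, harvest_lag = 0L,
                           noise_sd = 0, seed = NULL, name = "TSB") {
  if (inherits(drivers, "annual_series")) drivers <- list(drivers)
  p <- length(drivers)
  if (length(lags) != p || length(coeffs) != p) {
    stopf("drivers (%d), lags (%d) and coeffs (%d) must have equal length",
          p, length(lags), length(coeffs))
  }
  lags <- as.integer(lags)
  if (any(lags < 0L)) stopf("driver lags must be non-negative")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  yrs <- Reduce(intersect, lapply(drivers, function(s) s$years))
  if (!is.null(harvest)) yrs <- intersect(yrs, harvest$years)
  if (length(yrs) < 2L) stopf("driver/harvest series do not share years")
  yrs <- sort(yrs)
  with_seed(seed, {
    n <- length(yrs)
    noise <- if (noise_sd > 0) stats::rnorm(n, sd = noise_sd) else numeric(n)
    v <- noise
    for (k in seq_len(p)) {
      v <- v + coeffs[k] * value_at(drivers[[k]], yrs - lags[k])
    }
    if (!is.null(harvest) && harvest_coeff != 0) {
      v <- v + harvest_coeff * value_at(harvest, yrs - as.integer(harvest_lag))
    }
    annual_series(yrs, v, name = name)
  })
}

#' Configuration of a synthetic advective-lag scenario
#'
#' Describes the generative chain the analysis assumes: a red-noise upstream
#' index, downstream sections that lag it with attenuation and additive
#' noise, a stock driven linearly by lagged hydrography plus a lagged
#' harvest-rate effect, and a recruitment series leading the stock. The
#' defaults are a Barents-like configuration: travel times 3 y
#' (upstream -> inflow section) + 1 y (inflow -> Barents opening), a total
#' 7-y hydrography-to-stock response, a weak negative harvest effect
#' leading by 2 y, and recruitment leading stock by 2 y. Gains and noise
#' levels put the link correlations in the 0.5-0.8 band typical of observed
#' lagged peak correlations along this pathway.
#'
#' @param n_years simulated years (>= 30).
#' @param start_year first calendar year label.
#' @param upstream list: `name`, `ar1`, `sd` of the upstream index.
#' @param chain ordered list of links, each
#'   `list(source=, target=, lag_years=, gain=, noise_sd=)`; targets must be
#'   new names (the chain is acyclic by construction).
#' @param stock list: `name`, `drivers`, `lags`, `coeffs`, `harvest_coeff`,
#'   `harvest_lag`, `noise_sd`.
#' @param harvest list: `name`, `ar1`, `sd` of the independent red-noise
#'   harvest-rate series.
#' @param recruitment list: `name`, `lead` (years recruitment leads stock),
#'   `gain` (on the stock's driver signal), `noise_sd`.
#' @param seed root integer seed; all stages derive sub-seeds from it.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(n_years = 60L,
                            start_year = 1958L,
                            upstream = list(name = "AMO", ar1 = 0.6, sd = 1),
                            chain = list(
                              list(source = "AMO", target = "FSC",
                                   lag_years = 3L, gain = 0.8, noise_sd = 0.6),
                              list(source = "FSC", target = "BSO",
                                   lag_years = 1L, gain = 0.85, noise_sd = 0.53)),
                            stock = list(name = "TSB",
                                         drivers = c("FSC", "BSO"),
                                         lags = c(4L, 3L),
                                         coeffs = c(0.6, 0.5),
                                         harvest_coeff = -0.3,
                                         harvest_lag = 2L,
                                         noise_sd = 0.55),
                            harvest = list(name = "harvest_rate",
                                           ar1 = 0.5, sd = 1),
                            recruitment = list(name = "REC3", lead = 2L,
                                               gain = 0.4, noise_sd = 0.8),
                            seed = 1L) {
  cfg <- structure(list(n_years = as.integer(n_years),
                        start_year = as.integer(start_year),
                        upstream = upstream, chain = chain, stock = stock,
                        harvest = harvest, recruitment = recruitment,
                        seed = as.integer(seed)),
                   class = "scenario_config")
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  if (cfg$n_years < 30L) stopf("n_years must be >= 30")
  if (cfg$upstream$ar1 < 0 || cfg$upstream$ar1 >= 1) {
    stopf("upstream ar1 must be in [0, 1)")
  }
  known <- cfg$upstream$name
  all_lags <- integer()
  for (lk in cfg$chain) {
    if (!all(c("source", "target", "lag_years", "gain", "noise_sd") %in%
             names(lk))) {
      stopf("each chain link needs source, target, lag_years, gain, noise_sd")
    }
    if (!lk$source %in% known) {
      stopf("chain link source '%s' not yet defined (cyclic or out-of-order chain)",
            lk$source)
    }
    if (lk$target %in% known) {
      stopf("chain target '%s' already defined (cyclic chain)", lk$target)
    }
    if (lk$noise_sd < 0) stopf("link noise_sd must be >= 0")
    known <- c(known, lk$target)
    all_lags <- c(all_lags, lk$lag_years)
  }
  st <- cfg$stock
  if (length(st$drivers) != length(st$lags) ||
      length(st$drivers) != length(st$coeffs)) {
    stopf("stock drivers/lags/coeffs must have equal length")
  }
  if (!all(st$drivers %in% known)) stopf("unknown stock driver")
  if (st$noise_sd < 0) stopf("stock noise_sd must be >= 0")
  all_lags <- c(all_lags, st$lags, st$harvest_lag, cfg$recruitment$lead)
  if (any(all_lags < 0L)) stopf("all lags must be non-negative")
  if (any(all_lags >= cfg$n_years / 2)) {
    stopf("all lags must be < n_years/2")
  }
  invisible(cfg)
}

# ---------------------------------------------------------------------------
# Symbolic component algebra for closed-form ground truth.
#
# Every generated series is an exact linear combination of independent base
# sources (the upstream AR(1), the harvest AR(1), and one white-noise source
# per link/equation): series_t = sum_i coef_i * S_{t - lag_i}. Covariances
# between any two series at any relative lag therefore have a closed form,
# from which the theoretical peak lags/correlations and the multiple
# correlation of the stock equation are computed.

src_acov <- function(src, d) {
  if (src$type == "ar1") src$sd^2 * src$ar1^abs(d) else src$sd^2 * (d == 0)
}

# cov(A_{t-d}, B_t) for component tables a, b (columns source, lag, coef)
comp_cov <- function(a, b, d, sources) {
  tot <- 0
  for (i in seq_len(nrow(a))) {
    j <- which(b$source == a$source[i])
    for (jj in j) {
      tot <- tot + a$coef[i] * b$coef[jj] *
        src_acov(sources[[a$source[i]]], (d + a$lag[i]) - b$lag[jj])
    }
  }
  tot
}

comp_var <- function(a, sources) comp_cov(a, a, 0, sources)

comp_corr <- function(a, b, d, sources) {
  comp_cov(a, b, d, sources) / sqrt(comp_var(a, sources) * comp_var(b, sources))
}

comp_table <- function(source, lag, coef) {
  data.frame(source = source, lag = as.integer(lag), coef = coef,
             stringsAsFactors = FALSE)
}

shift_scale <- function(a, lag, coef) {
  a$lag <- a$lag + as.integer(lag)
  a$coef <- a$coef * coef
  a
}

#' Realize a full synthetic scenario with ground truth
#'
#' Simulates the configured chain (upstream index, downstream sections,
#' independent harvest-rate series, stock, recruitment) and returns both the
#' dataset and a `scenario_truth` object carrying the closed-form peak lags,
#' peak correlations and multiple correlations implied by the configured
#' gains, AR(1) coefficients and noise levels. Fully reproducible from the
#' config's root seed.
#'
#' Recruitment is generated as the stock's hydrographic driver signal
#' evaluated `recruitment$lead` years later, scaled by `recruitment$gain`
#' and degraded with independent noise, so it leads the stock and carries a
#' lower signal fraction.
#'
#' @param config a [scenario_config()].
#' @return a list with components `series` (named list of [annual_series]),
#'   `truth` (class `scenario_truth`) and `config`.
#' @export
make_scenario <- function(config = scenario_config()) {
  validate_scenario_config(config)
  seed <- config$seed
  up <- config$upstream

  series <- list()
  sources <- list()
  comps <- list()

  series[[up$name]] <- simulate_upstream_index(
    config$n_years, up$ar1, up$sd, seed = derive_seed(seed, 1L),
    start_year = config$start_year, name = up$name)
  sources[[up$name]] <- list(type = "ar1", ar1 = up$ar1, sd = up$sd)
  comps[[up$name]] <- comp_table(up$name, 0L, 1)

  k <- 1L
  links <- data.frame()
  for (lk in config$chain) {
    k <- k + 1L
    series[[lk$target]] <- propagate_anomaly(
      series[[lk$source]], lk$lag_years, lk$gain, lk$noise_sd,
      seed = derive_seed(seed, k), name = lk$target)
    noise_name <- paste0("noise_", lk$target)
    sources[[noise_name]] <- list(type = "white", sd = lk$noise_sd)
    comps[[lk$target]] <- rbind(
      shift_scale(comps[[lk$source]], lk$lag_years, lk$gain),
      comp_table(noise_name, 0L, 1))
    links <- rbind(links, data.frame(
      source = lk$source, target = lk$target, lag = lk$lag_years,
      stringsAsFactors = FALSE))
  }

  hv <- config$harvest
  series[[hv$name]] <- simulate_upstream_index(
    config$n_years, hv$ar1, hv$sd, seed = derive_seed(seed, 90L),
    start_year = config$start_year, name = hv$name)
  sources[[hv$name]] <- list(type = "ar1", ar1 = hv$ar1, sd = hv$sd)
  comps[[hv$name]] <- comp_table(hv$name, 0L, 1)

  st <- config$stock
  series[[st$name]] <- simulate_stock(
    drivers = series[st$drivers], lags = st$lags, coeffs = st$coeffs,
    harvest = series[[hv$name]], harvest_coeff = st$harvest_coeff,
    harvest_lag = st$harvest_lag, noise_sd = st$noise_sd,
    seed = derive_seed(seed, 91L), name = st$name)
  sources[[paste0("noise_", st$name)]] <- list(type = "white", sd = st$noise_sd)
  driver_signal <- do.call(rbind, lapply(seq_along(st$drivers), function(i) {
    shift_scale(comps[[st$drivers[i]]], st$lags[i], st$coeffs[i])
  }))
  stock_comp <- rbind(driver_signal,
                      if (st$harvest_coeff != 0)
                        shift_scale(comps[[hv$name]], st$harvest_lag,
                                    st$harvest_coeff),
                      comp_table(paste0("noise_", st$name), 0L, 1))
  comps[[st$name]] <- stock_comp

  # Recruitment: driver signal led by `lead` years plus independent noise.
  rc <- config$recruitment
  yrs <- series[[st$name]]$years
  rec_sig <- rep(0, length(yrs))
  for (i in seq_along(st$drivers)) {
    rec_sig <- rec_sig +
      st$coeffs[i] * value_at(series[[st$drivers[i]]],
                              yrs + rc$lead - st$lags[i])
  }
  rec_v <- with_seed(derive_seed(seed, 92L), {
    rc$gain * rec_sig +
      (if (rc$noise_sd > 0) stats::rnorm(length(yrs), sd = rc$noise_sd)
       else 0)
  })
  series[[rc$name]] <- annual_series(yrs, rec_v, name = rc$name)
  sources[[paste0("noise_", rc$name)]] <- list(type = "white", sd = rc$noise_sd)
  comps[[rc$name]] <- rbind(
    shift_scale(driver_signal, -rc$lead, rc$gain),
    comp_table(paste0("noise_", rc$name), 0L, 1))

  truth <- build_truth(config, links, comps, sources, driver_signal)
  list(series = series, truth = truth, config = config)
}

build_truth <- function(config, links, comps, sources, driver_signal) {
  up <- config$upstream$name
  st <- config$stock

  per_link <- do.call(rbind, lapply(seq_len(nrow(links)), function(i) {
    a <- comps[[links$source[i]]]
    b <- comps[[links$target[i]]]
    prof <- vapply(0:15, function(d) comp_corr(a, b, d, sources), numeric(1L))
    data.frame(source = links$source[i], target = links$target[i],
               configured_lag = links$lag[i],
               peak_lag = which.max(abs(prof)) - 1L,
               peak_r = prof[which.max(abs(prof))],
               stringsAsFactors = FALSE)
  }))

  targets <- setdiff(names(comps), up)
  upstream_to <- do.call(rbind, lapply(targets, function(tg) {
    prof <- vapply(0:15, function(d) comp_corr(comps[[up]], comps[[tg]], d,
                                               sources), numeric(1L))
    data.frame(target = tg, peak_lag = which.max(abs(prof)) - 1L,
               peak_r = prof[which.max(abs(prof))], stringsAsFactors = FALSE)
  }))

  v_drivers <- comp_var(driver_signal, sources)
  v_harvest <- if (st$harvest_coeff != 0) {
    comp_var(shift_scale(comps[[config$harvest$name]], st$harvest_lag,
                         st$harvest_coeff), sources)
  } else 0
  v_noise <- st$noise_sd^2
  v_total <- v_drivers + v_harvest + v_noise
  structure(list(
    config = config,
    links = per_link,
    upstream_to = upstream_to,
    stock_var = v_total,
    # multiple correlation of a model using only the hydrographic drivers
    rho_drivers = sqrt(v_drivers / v_total),
    # ... and of the full equation including the harvest term
    rho_full = sqrt((v_drivers + v_harvest) / v_total),
    r2_drivers = v_drivers / v_total,
    r2_full = (v_drivers + v_harvest) / v_total,
    components = comps,
    sources = sources),
    class = "scenario_truth")
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat("<scenario_truth>\n links:\n")
  print(x$links, row.names = FALSE)
  cat(" upstream ->\n")
  print(x$upstream_to, row.names = FALSE)
  cat(sprintf(" stock multiple rho: %.3f (drivers only), %.3f (with harvest)\n",
              x$rho_drivers, x$rho_full))
  invisible(x)
}

#' Closed-form multiple correlation of the scenario's stock equation
#'
#' @param truth a `scenario_truth` from [make_scenario()].
#' @param include_harvest include the harvest term among the predictors?
#' @return the theoretical multiple correlation coefficient.
#' @export
theoretical_multiple_r <- function(truth, include_harvest = FALSE) {
  stopifnot(inherits(truth, "scenario_truth"))
  if (include_harvest) truth$rho_full else truth$rho_drivers
}

#' Closed-form multiple correlation of an arbitrary lagged predictor set
#'
#' Population multiple correlation of regressing the stock on the named
#' scenario series at the given leads, `rho^2 = c' C^{-1} c / var(y)`,
#' where `C` is the population covariance matrix of the lagged predictors
#' and `c` their covariance with the stock - all available in closed form
#' from the generator's component decomposition. This is the ceiling a
#' (possibly lag-misspecified) regression can reach on that predictor set.
#'
#' @param truth a `scenario_truth`.
#' @param predictors character vector of scenario series names.
#' @param leads integer lead per predictor (recycled).
#' @param predictand predictand series name (default the stock).
#' @return the theoretical multiple correlation.
#' @export
theoretical_design_r <- function(truth, predictors, leads,
                                 predictand = truth$config$stock$name) {
  stopifnot(inherits(truth, "scenario_truth"))
  comps <- truth$components
  src <- truth$sources
  missing <- setdiff(c(predictors, predictand), names(comps))
  if (length(missing)) {
    stopf("unknown scenario series: %s", paste(missing, collapse = ", "))
  }
  p <- length(predictors)
  leads <- as.integer(rep_len(leads, p))
  C <- matrix(0, p, p)
  cv <- numeric(p)
  for (j in seq_len(p)) {
    for (k in seq_len(p)) {
      C[j, k] <- comp_cov(comps[[predictors[j]]], comps[[predictors[k]]],
                          leads[j] - leads[k], src)
    }
    cv[j] <- comp_cov(comps[[predictors[j]]], comps[[predictand]],
                      leads[j], src)
  }
  vy <- comp_var(comps[[predictand]], src)
  sqrt(drop(crossprod(cv, solve(C, cv))) / vy)
}

#' Write every series of a scenario to a directory of CSV files
#'
#' One `<name>.csv` per series in [write_series()] format; byte-identical
#' across reruns with the same config and seed.
#'
#' @param scenario a [make_scenario()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(scenario$series, function(s) {
    p <- file.path(dir, paste0(s$name, ".csv"))
    write_series(s, p)
    p
  }, character(1L))
  invisible(paths)
}
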