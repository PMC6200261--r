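#' Default run configuration for the bundled synthetic scenario
#'
#' A complete `run_config` list driving the whole analysis on a simulated
#' Barents-like dataset: scenario parameters, predictor set, lead, baseline
#' window, cross-validation settings, benchmark lags and attribution lags.
#' See `inst/extdata/barents_scenario.yaml` for the same content as a
#' config file.
#'
#' @param seed root seed for the run.
#' @return a named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    mode = "synthetic",
    scenario = list(),               # overrides for scenario_config()
    predictand = "TSB",
    predictors = c("FSC", "BSO", "AMO"),
    screen_predictors = c("AMO", "FSC", "BSO"),
    lead = 7L,
    lag_min = 0L,
    lag_max = 10L,
    detrend_screening = TRUE,
    anomalize = TRUE,
    baseline = NULL,                 # NULL = full span of each series
    n_iter = 500L,
    fit_frac = 0.8,
    n_surrogates = 500L,
    alpha = 0.05,
    persistence_lags = 1:7,
    attribution_lags = 0:5,
    highpass_cutoff = 5L,
    seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror [default_run_config()]; unspecified keys keep their
#' defaults. The `scenario` block holds overrides for [scenario_config()]
#' (synthetic mode); a `series` block of `name: path` entries switches to
#' file-driven mode, with optional `catch`/`harvest_rate` roles used for
#' error attribution.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  for (nm in c("lead", "lag_min", "lag_max", "n_iter", "n_surrogates",
               "seed", "highpass_cutoff")) {
    cfg[[nm]] <- as.integer(cfg[[nm]])
  }
  cfg$persistence_lags <- as.integer(unlist(cfg$persistence_lags))
  cfg$attribution_lags <- as.integer(unlist(cfg$attribution_lags))
  if (is.null(cfg$seed) || is.na(cfg$seed)) stopf("config must set a seed")
  cfg
}

# Materialize the input series for a run: simulate the scenario, or read
# the configured files. Returns list(series=..., truth=or NULL).
load_run_inputs <- function(config) {
  if (identical(config$mode, "synthetic")) {
    sc_args <- config$scenario %||% list()
    sc_args$seed <- sc_args$seed %||% config$seed
    sc <- do.call(scenario_config, normalize_scenario_args(sc_args))
    scen <- make_scenario(sc)
    list(series = scen$series, truth = scen$truth, scenario = sc)
  } else {
    if (is.null(config$series)) stopf("file mode needs a `series:` block")
    paths <- unlist(config$series)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stopf("series file(s) not found: %s", paste(missing, collapse = ", "))
    }
    series <- lapply(names(paths), function(nm) read_series(paths[[nm]], nm))
    names(series) <- names(paths)
    list(series = series, truth = NULL, scenario = NULL)
  }
}

# YAML gives plain lists; coerce the nested scenario blocks to the shapes
# scenario_config() expects.
normalize_scenario_args <- function(a) {
  num_fields <- c("n_years", "start_year", "seed")
  for (f in intersect(num_fields, names(a))) a[[f]] <- as.integer(a[[f]])
  if (!is.null(a$stock)) {
    a$stock$drivers <- as.character(unlist(a$stock$drivers))
    a$stock$lags <- as.integer(unlist(a$stock$lags))
    a$stock$coeffs <- as.double(unlist(a$stock$coeffs))
  }
  a
}

#' Lagged-correlation screening of candidate predictors
#'
#' Computes the full lag profile of every screening predictor against the
#' predictand (each predictor leading), with peak lag and random phase
#' significance - the machinery behind a lagged peak-correlation table.
#'
#' @param series named list of [annual_series].
#' @param predictand name of the predictand series.
#' @param predictors names of the candidate predictors.
#' @param lag_min,lag_max search range in years.
#' @param detrend detrend aligned segments before correlating?
#' @param n_surrogates surrogates for per-lag significance (0 to skip).
#' @param alpha significance level.
#' @param seed integer seed or `NULL`.
#' @return a `screening_table` data frame (predictor, predictand, peak_lag,
#'   peak_r, n, p_value, significant) with the per-predictor profiles in
#'   attribute `profiles`.
#' @export
run_screening <- function(series, predictand = "TSB",
                          predictors = setdiff(names(series), predictand),
                          lag_min = 0L, lag_max = 10L, detrend = TRUE,
                          n_surrogates = 500L, alpha = 0.05, seed = NULL) {
  if (!predictand %in% names(series)) {
    stopf("predictand '%s' not among the series", predictand)
  }
  missing <- setdiff(predictors, names(series))
  if (length(missing)) {
    stopf("screening predictors not found: %s", paste(missing, collapse = ", "))
  }
  y <- series[[predictand]]
  profiles <- list()
  rows <- list()
  for (i in seq_along(predictors)) {
    nm <- predictors[i]
    prof <- lagged_correlation(series[[nm]], y, lag_min, lag_max,
                               detrend = detrend,
                               n_surrogates = n_surrogates, alpha = alpha,
                               seed = derive_seed(seed, i))
    pk <- peak_lag(prof)
    at <- prof[prof$lag == pk$lag, ]
    profiles[[nm]] <- prof
    rows[[i]] <- data.frame(predictor = nm, predictand = predictand,
                            peak_lag = pk$lag, peak_r = pk$r, n = at$n,
                            p_value = at$p_value,
                            significant = at$significant,
                            stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows),
            class = c("screening_table", "data.frame"), profiles = profiles)
}

#' Fit, cross-validate and forecast from a configured predictor set
#'
#' The central prediction step: aligns the (optionally anomaly-transformed)
#' predictand with its predictors at a common lead `l`, fits the full-data
#' lag-l regression, runs residual diagnostics and Monte-Carlo 80/20
#' cross-validation, and produces the retrospective forecast over all
#' predictable past years plus the future forecast extending `l` years past
#' the last observation (the horizon the lead buys). The cross-validation
#' ensemble envelope is attached to both forecasts as `spread_lwr`
#' / `spread_upr`; the headline forecast itself comes from the model fit on
#' all available data.
#'
#' @param series named list of [annual_series].
#' @param predictand predictand series name.
#' @param predictors predictor series names.
#' @param lead common lead in years (7 for biomass, 5 for recruitment in
#'   the motivating application).
#' @param anomalize convert all series to anomalies first?
#' @param baseline `c(start, end)` baseline window for anomalies, or `NULL`
#'   for each series' full span.
#' @param n_iter,fit_frac cross-validation settings.
#' @param seed integer seed or `NULL`.
#' @return list with `model`, `design`, `diagnostics`, `skill`
#'   (a `skill_report`), `retrospective` and `future` forecasts.
#' @export
run_prediction <- function(series, predictand = "TSB",
                           predictors = c("FSC", "BSO", "AMO"), lead = 7L,
                           anomalize = TRUE, baseline = NULL,
                           n_iter = 1000L, fit_frac = 0.8, seed = NULL) {
  used <- c(predictand, predictors)
  missing <- setdiff(used, names(series))
  if (length(missing)) {
    stopf("series not found: %s", paste(missing, collapse = ", "))
  }
  ser <- series[used]
  if (anomalize) {
    ser <- lapply(ser, function(s) {
      to_anomalies(s, baseline[1L] %||% NULL, baseline[2L] %||% NULL)
    })
  }
  design <- align(ser[[predictand]], ser[predictors], leads = lead)
  model <- fit_model(design)
  diagnostics <- diagnose(model)
  if (!all(diagnostics$flags)) {
    warning(sprintf("residual diagnostics flag(s) failed (%s); proceeding",
                    paste(names(which(!diagnostics$flags)), collapse = ", ")),
            call. = FALSE)
  }
  skill <- cross_validate(design, n_iter = n_iter, fit_frac = fit_frac,
                          seed = derive_seed(seed, 11L))
  fc <- stats::predict(model, ser[predictors])
  fc$spread_lwr <- fc$spread_upr <- NA_real_
  m <- match(fc$year, skill$spread$year)
  fc$spread_lwr[!is.na(m)] <- skill$spread$lwr[m[!is.na(m)]]
  fc$spread_upr[!is.na(m)] <- skill$spread$upr[m[!is.na(m)]]
  retro <- restore_forecast_attrs(fc[!fc$future, , drop = FALSE], fc)
  future <- restore_forecast_attrs(fc[fc$future, , drop = FALSE], fc)
  list(model = model, design = design, diagnostics = diagnostics,
       skill = skill, retrospective = retro, future = future,
       observed = ser[[predictand]])
}

# Subsetting a data.frame subclass drops custom attributes; copy them back.
restore_forecast_attrs <- function(df, template) {
  for (a in c("provenance", "level", "interval")) {
    attr(df, a) <- attr(template, a)
  }
  class(df) <- class(template)
  rownames(df) <- NULL
  df
}

#' Attribute prediction error to fishing pressure
#'
#' Computes the retrospective prediction error (observed minus predicted)
#' and its lagged correlation with harvest-rate anomalies (harvest leading
#' the error), reusing the lag-analysis machinery. A persistent negative
#' correlation at positive lead means that anomalously low fishing pressure
#' is followed by under-predicted stock a few years later - exactly the
#' signature expected when the regression omits harvest information.
#'
#' @param retrospective a retrospective `stock_forecast`.
#' @param observed the observed predictand [annual_series].
#' @param harvest_rate_series harvest-rate [annual_series].
#' @param lag_range lags (harvest leading) to profile, default 0:5.
#' @param detrend detrend before correlating (default `FALSE`: the error
#'   and harvest anomalies are compared as-is).
#' @param n_surrogates surrogates for per-lag significance.
#' @param alpha significance level.
#' @param seed integer seed or `NULL`.
#' @return a `lag_corr_profile` of harvest leading the prediction error.
#' @export
error_attribution <- function(retrospective, observed, harvest_rate_series,
                              lag_range = 0:5, detrend = FALSE,
                              n_surrogates = 500L, alpha = 0.05,
                              seed = NULL) {
  stopifnot(inherits(retrospective, "stock_forecast"),
            inherits(observed, "annual_series"),
            inherits(harvest_rate_series, "annual_series"))
  obs <- value_at(observed, retrospective$year)
  err <- obs - retrospective$fit
  ok <- !is.na(err)
  if (sum(ok) < 15L) stopf("error_attribution needs >= 15 overlapping years")
  error_series <- annual_series(retrospective$year[ok], err[ok],
                                name = "prediction_error")
  harvest_anom <- to_anomalies(harvest_rate_series, NULL, NULL)
  lagged_correlation(harvest_anom, error_series,
                     l_min = min(lag_range), l_max = max(lag_range),
                     detrend = detrend, n_surrogates = n_surrogates,
                     alpha = alpha, seed = seed)
}

#' Skill of the high-pass filtered predictions
#'
#' Correlates high-pass filtered (running-mean-removed) predictions with
#' equally filtered observations and reports it next to the unfiltered
#' correlation. A large drop reveals that the predictive skill originates
#' from multi-year, low-frequency variations rather than year-to-year
#' fluctuations.
#'
#' @param retrospective a retrospective `stock_forecast`.
#' @param observed observed [annual_series].
#' @param cutoff filter cut-off width in years (default 5).
#' @return list with `r_highpass`, `r_unfiltered` and `cutoff`.
#' @export
run_highpass_skill <- function(retrospective, observed, cutoff = 5L) {
  stopifnot(inherits(retrospective, "stock_forecast"),
            inherits(observed, "annual_series"))
  yrs <- retrospective$year
  pred <- annual_series(yrs, retrospective$fit, name = "prediction")
  obs_v <- value_at(observed, yrs)
  ok <- !is.na(obs_v)
  obs <- annual_series(yrs[ok], obs_v[ok], name = observed$name)
  hp_o <- highpass(obs, cutoff)
  hp_p <- highpass(pred, cutoff)
  common <- intersect(hp_o$years, hp_p$years)
  list(r_highpass = anomaly_correlation(value_at(hp_o, common),
                                        value_at(hp_p, common)),
       r_unfiltered = anomaly_correlation(value_at(obs, common),
                                          value_at(pred, common)),
       cutoff = as.integer(cutoff))
}

#' Run the full analysis and write a reproducible report
#'
#' Orchestrates scenario simulation (or file loading), predictor screening,
#' model fitting with diagnostics, cross-validated skill with
#' random-chance and persistence benchmarks, retrospective and future
#' forecasts, harvest-rate error attribution and high-pass skill, writing
#' every table as CSV plus a plain-text summary to `out_dir`. All
#' randomness flows from `config$seed` via deterministic stream splitting,
#' so a rerun with the same config yields byte-identical files.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param seed optional override of `config$seed`.
#' @return invisibly, a `run_report` list with all computed objects.
#' @export
run_all <- function(config = default_run_config(), out_dir = NULL,
                    seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  inputs <- load_run_inputs(config)
  series <- inputs$series

  screening <- run_screening(series, config$predictand,
                             config$screen_predictors %||% config$predictors,
                             lag_min = config$lag_min,
                             lag_max = config$lag_max,
                             detrend = config$detrend_screening,
                             n_surrogates = config$n_surrogates,
                             alpha = config$alpha,
                             seed = derive_seed(config$seed, 101L))

  pred <- run_prediction(series, config$predictand, config$predictors,
                         lead = config$lead, anomalize = config$anomalize,
                         baseline = config$baseline, n_iter = config$n_iter,
                         fit_frac = config$fit_frac,
                         seed = derive_seed(config$seed, 102L))

  bench <- benchmark_comparison(pred$design, pred$observed,
                                persistence_lags = config$persistence_lags,
                                n_iter = config$n_iter,
                                fit_frac = config$fit_frac,
                                seed = derive_seed(config$seed, 103L))

  attribution <- NULL
  if ("harvest_rate" %in% names(series)) {
    attribution <- error_attribution(pred$retrospective, pred$observed,
                                     series$harvest_rate,
                                     lag_range = config$attribution_lags,
                                     n_surrogates = config$n_surrogates,
                                     alpha = config$alpha,
                                     seed = derive_seed(config$seed, 104L))
  }

  hp <- run_highpass_skill(pred$retrospective, pred$observed,
                           cutoff = config$highpass_cutoff)

  report <- structure(list(config = config, truth = inputs$truth,
                           series = series, screening = screening,
                           prediction = pred, benchmarks = bench,
                           attribution = attribution, highpass = hp),
                      class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  invisible(report)
}

write_run_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- report$config
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)

  scr <- as.data.frame(report$screening)
  scr$peak_r <- format_num(scr$peak_r)
  scr$p_value <- format_num(scr$p_value)
  utils::write.csv(scr, file.path(out_dir, "screening.csv"),
                   row.names = FALSE, na = "", quote = FALSE)

  write_skill(report$benchmarks, file.path(out_dir, "skill.csv"))
  pers <- report$benchmarks$persistence
  pers$r <- format_num(pers$r)
  pers$beta <- format_num(pers$beta)
  utils::write.csv(pers, file.path(out_dir, "persistence.csv"),
                   row.names = FALSE, quote = FALSE)

  write_forecast(report$prediction$retrospective,
                 file.path(out_dir, "forecast_retrospective.csv"))
  write_forecast(report$prediction$future,
                 file.path(out_dir, "forecast_future.csv"))
  if (!is.null(report$attribution)) {
    write_profile(report$attribution, file.path(out_dir, "attribution.csv"))
  }

  lines <- c(
    "codcast run report",
    sprintf("package version: %s",
            as.character(utils::packageVersion("codcast"))),
    sprintf("seed: %d", cfg$seed),
    sprintf("config md5: %s", unname(tools::md5sum(cfg_path))),
    sprintf("mode: %s", cfg$mode),
    sprintf("model: %s ~ %s (lead %d)", cfg$predictand,
            paste(cfg$predictors, collapse = " + "), cfg$lead),
    sprintf("design rows: %d (%d-%d)", length(report$prediction$design$y),
            min(report$prediction$design$years),
            max(report$prediction$design$years)),
    sprintf("cross-validation: %d x %.0f/%.0f", cfg$n_iter,
            100 * cfg$fit_frac, 100 * (1 - cfg$fit_frac)),
    sprintf("median prediction-period r: %.4f",
            stats::median(report$prediction$skill$values$r_pred)),
    sprintf("median prediction-period beta: %.4f",
            stats::median(report$prediction$skill$values$beta_pred)),
    sprintf("random-chance median prediction-period r: %.4f",
            stats::median(report$benchmarks$rc$values$r_pred)),
    sprintf("Durbin-Watson: %.4f (residual lag-1 r = %.4f)",
            report$prediction$diagnostics$dw,
            report$prediction$diagnostics$resid_ac1),
    sprintf("high-pass (%d-y) r: %.4f (unfiltered %.4f)",
            report$highpass$cutoff, report$highpass$r_highpass,
            report$highpass$r_unfiltered),
    if (!is.null(report$attribution)) {
      pk <- peak_lag(report$attribution)
      sprintf("harvest attribution peak: r = %.4f at lag %d", pk$r, pk$lag)
    },
    sprintf("future forecast: %d year(s) to %d",
            nrow(report$prediction$future),
            if (nrow(report$prediction$future)) {
              max(report$prediction$future$year)
            } else NA_integer_))
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n screening:\n")
  print(as.data.frame(x$screening), row.names = FALSE, digits = 3)
  cat(sprintf(" median prediction-period r = %.3f, beta = %.3f\n",
              stats::median(x$prediction$skill$values$r_pred),
              stats::median(x$prediction$skill$values$beta_pred)))
  if (!is.null(x$attribution)) {
    pk <- peak_lag(x$attribution)
    cat(sprintf(" harvest attribution: peak r = %.3f at lag %d\n", pk$r,
                pk$lag))
  }
  invisible(x)
}

#' Command-line entry point
#'
#' Thin argument-parsing layer over the pipeline, used by the
#' `inst/cli/codcast.R` script: subcommands `simulate` (write the scenario
#' series as CSV), `screen`, `predict`, `attribute` and `all` (full run),
#' each accepting `--config PATH`, `--seed INT` and `--out DIR`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, 0 on success (invisibly).
#' @export
codcast_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: codcast.R <simulate|screen|predict|attribute|all>",
                 "[--config PATH] [--seed INT] [--out DIR]")
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    message(usage)
    return(invisible(if (length(args)) 0L else 1L))
  }
  cmd <- args[1L]
  opts <- list(config = NULL, seed = NULL, out = "codcast_out")
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!rest[i] %in% c("--config", "--seed", "--out") ||
        i == length(rest)) {
      message("unknown or incomplete option: ", rest[i], "\n", usage)
      return(invisible(1L))
    }
    opts[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  cfg <- tryCatch({
    base <- if (is.null(opts$config)) default_run_config()
            else read_run_config(opts$config)
    if (!is.null(opts$seed)) base$seed <- as.integer(opts$seed)
    base
  }, error = function(e) {
    message("config error: ", conditionMessage(e))
    NULL
  })
  if (is.null(cfg)) return(invisible(1L))
  status <- tryCatch({
    switch(cmd,
      simulate = {
        inputs <- load_run_inputs(cfg)
        write_scenario(list(series = inputs$series), opts$out)
        message("wrote ", length(inputs$series), " series to ", opts$out)
        0L
      },
      screen = {
        inputs <- load_run_inputs(cfg)
        scr <- run_screening(inputs$series, cfg$predictand,
                             cfg$screen_predictors %||% cfg$predictors,
                             lag_min = cfg$lag_min, lag_max = cfg$lag_max,
                             detrend = cfg$detrend_screening,
                             n_surrogates = cfg$n_surrogates,
                             alpha = cfg$alpha,
                             seed = derive_seed(cfg$seed, 101L))
        if (!dir.exists(opts$out)) dir.create(opts$out, recursive = TRUE)
        df <- as.data.frame(scr)
        df$peak_r <- format_num(df$peak_r)
        df$p_value <- format_num(df$p_value)
        utils::write.csv(df, file.path(opts$out, "screening.csv"),
                         row.names = FALSE, na = "", quote = FALSE)
        print(scr)
        0L
      },
      predict = ,
      attribute = ,
      all = {
        rep <- run_all(cfg, out_dir = opts$out)
        print(rep)
        0L
      },
      {
        message("unknown subcommand: ", cmd, "\n", usage)
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
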