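#' Variance-ratio Brier score
#'
#' `beta = 1 - var(observed - predicted) / var(observed)`, both variances
#' with the `n - 1` denominator. `beta = 1` for a perfect forecast,
#' `beta = 0` when the error variance equals the predictand variance (a
#' climatological-mean forecast), and it is unbounded below. Despite the
#' shared name, this is a deterministic variance-ratio score, not the
#' probabilistic Brier score.
#'
#' @param observed,predicted paired numeric vectors (NA pairs dropped).
#' @return the score `beta`.
#' @export
brier_score <- function(observed, predicted) {
  ok <- !is.na(observed) & !is.na(predicted)
  o <- observed[ok]
  p <- predicted[ok]
  if (length(o) < 3L) stopf("brier_score needs >= 3 paired values")
  vo <- stats::var(o)
  if (vo == 0) stopf("brier_score undefined: observed values have zero variance")
  1 - stats::var(o - p) / vo
}

#' Anomaly correlation coefficient
#'
#' Pearson correlation between paired observations and predictions.
#'
#' @inheritParams brier_score
#' @return the correlation `r`.
#' @export
anomaly_correlation <- function(observed, predicted) {
  ok <- !is.na(observed) & !is.na(predicted)
  o <- observed[ok]
  p <- predicted[ok]
  if (length(o) < 3L) stopf("anomaly_correlation needs >= 3 paired values")
  if (stats::var(o) == 0 || stats::var(p) == 0) {
    stopf("anomaly_correlation undefined: zero variance")
  }
  stats::cor(o, p)
}

# One Monte-Carlo CV pass over a prepared design matrix. Returns NULL when
# the draw must be redone (degenerate split). `shuffle` permutes each
# predictor column first (the random-chance protocol).
cv_iteration <- function(X, y, n_fit, shuffle = FALSE) {
  n <- length(y)
  p <- ncol(X) - 1L
  if (shuffle) {
    for (k in 2L:ncol(X)) X[, k] <- X[sample.int(n), k]
  }
  idx <- sample.int(n, n_fit)
  test <- setdiff(seq_len(n), idx)
  if (length(test) < 3L) return(NULL)
  fit <- stats::lm.fit(X[idx, , drop = FALSE], y[idx])
  if (fit$rank < ncol(X)) return(NULL)
  beta <- fit$coefficients
  yhat <- drop(X %*% beta)
  if (stats::var(y[test]) == 0 || stats::var(yhat[test]) == 0 ||
      stats::var(yhat[idx]) == 0) {
    return(NULL)
  }
  list(coef = beta, yhat = yhat,
       r_fit = stats::cor(y[idx], yhat[idx]),
       r_pred = stats::cor(y[test], yhat[test]),
       beta_fit = 1 - stats::var(y[idx] - yhat[idx]) / stats::var(y[idx]),
       beta_pred = 1 - stats::var(y[test] - yhat[test]) / stats::var(y[test]))
}

cv_engine <- function(design, n_iter, fit_frac, shuffle = FALSE) {
  X <- cbind(1, design$X)
  y <- design$y
  n <- length(y)
  n_fit <- round(fit_frac * n)
  if (n < 20L) stopf("cross-validation needs >= 20 design rows")
  coefs <- matrix(NA_real_, ncol(X), n_iter,
                  dimnames = list(c("(Intercept)", design$predictors), NULL))
  preds <- matrix(NA_real_, n, n_iter)
  r_fit <- r_pred <- b_fit <- b_pred <- numeric(n_iter)
  redraws <- 0L
  i <- 1L
  attempts <- 0L
  while (i <= n_iter) {
    attempts <- attempts + 1L
    if (attempts > 10L * n_iter) {
      stopf("cross-validation: redraw limit (%d) exceeded", 10L * n_iter)
    }
    it <- cv_iteration(X, y, n_fit, shuffle = shuffle)
    if (is.null(it)) {
      redraws <- redraws + 1L
      next
    }
    coefs[, i] <- it$coef
    preds[, i] <- it$yhat
    r_fit[i] <- it$r_fit
    r_pred[i] <- it$r_pred
    b_fit[i] <- it$beta_fit
    b_pred[i] <- it$beta_pred
    i <- i + 1L
  }
  list(coefs = coefs, preds = preds, r_fit = r_fit, r_pred = r_pred,
       beta_fit = b_fit, beta_pred = b_pred, redraws = redraws)
}

med_iqr <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  c(median = q[2L], q25 = q[1L], q75 = q[3L])
}

skill_table <- function(res) {
  rows <- list(c("r", "fitting", med_iqr(res$r_fit)),
               c("r", "prediction", med_iqr(res$r_pred)),
               c("beta", "fitting", med_iqr(res$beta_fit)),
               c("beta", "prediction", med_iqr(res$beta_pred)))
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(metric = r[[1L]], period = r[[2L]],
               median = as.double(r[[3L]]), q25 = as.double(r[[4L]]),
               q75 = as.double(r[[5L]]), stringsAsFactors = FALSE)
  }))
  out
}

#' Monte-Carlo 80/20 cross-validation of a lag-l regression
#'
#' Each iteration draws a uniform random `fit_frac` subset of the design
#' rows (without replacement; rows are years, non-contiguous subsets are
#' allowed), fits the model on it, and scores anomaly correlation and Brier
#' score on both the fitting subset and the held-out prediction subset.
#' Medians and inter-quartile ranges over the iterations summarize the
#' skill; the per-iteration coefficient ensemble and the per-year envelope
#' (min-max) of the ensemble predictions are returned for spread shading.
#' Draws whose prediction subset has fewer than 3 rows, or is otherwise
#' degenerate, are redrawn (counted, limit `10 * n_iter`).
#'
#' @param design an [align()] result with >= 20 rows.
#' @param n_iter number of resamples (default 1000).
#' @param fit_frac fraction of rows in the fitting period (default 0.8).
#' @param seed integer seed or `NULL`.
#' @return a `skill_report`: `metrics` table (metric, period, median, q25,
#'   q75), `values` (per-iteration vectors), `coefficients` matrix,
#'   `spread` data frame (year, lwr, upr), `n_iter`, `fit_frac`, `redraws`,
#'   `seed`.
#' @export
cross_validate <- function(design, n_iter = 1000L, fit_frac = 0.8,
                           seed = NULL) {
  stopifnot(inherits(design, "aligned_design"))
  res <- with_seed(seed, cv_engine(design, n_iter, fit_frac))
  structure(list(metrics = skill_table(res),
                 values = res[c("r_fit", "r_pred", "beta_fit", "beta_pred")],
                 coefficients = res$coefs,
                 spread = data.frame(year = design$years,
                                     lwr = apply(res$preds, 1L, min),
                                     upr = apply(res$preds, 1L, max)),
                 n_iter = n_iter, fit_frac = fit_frac,
                 redraws = res$redraws, seed = seed),
            class = "skill_report")
}

#' @export
print.skill_report <- function(x, ...) {
  cat(sprintf("<skill_report> %d x %.0f%%/%.0f%% resamples (%d redraws)\n",
              x$n_iter, 100 * x$fit_frac, 100 * (1 - x$fit_frac), x$redraws))
  print(x$metrics, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compare model skill against random-chance and persistence benchmarks
#'
#' Runs the Monte-Carlo cross-validation for the model, repeats the same
#' protocol with independently permuted predictor columns each iteration
#' (the random-chance null), and computes lagged persistence skill (r and
#' beta of forecasting year `i` with the observation of year `i - l`) for
#' each requested lag.
#'
#' @param design an [align()] result.
#' @param observed the predictand [annual_series] (for persistence).
#' @param persistence_lags integer lags (default 1:7).
#' @param n_iter resamples for model and random-chance skill.
#' @param fit_frac fitting fraction.
#' @param seed integer seed or `NULL`.
#' @return a `benchmark_report`: `model` and `rc` skill_reports and a
#'   `persistence` data frame (lag, r, beta, n).
#' @export
benchmark_comparison <- function(design, observed, persistence_lags = 1:7,
                                 n_iter = 1000L, fit_frac = 0.8,
                                 seed = NULL) {
  stopifnot(inherits(design, "aligned_design"),
            inherits(observed, "annual_series"))
  model <- cross_validate(design, n_iter, fit_frac,
                          seed = derive_seed(seed, 1L))
  rc_res <- with_seed(derive_seed(seed, 2L),
                      cv_engine(design, n_iter, fit_frac, shuffle = TRUE))
  rc <- structure(list(metrics = skill_table(rc_res),
                       values = rc_res[c("r_fit", "r_pred", "beta_fit",
                                         "beta_pred")],
                       coefficients = rc_res$coefs,
                       spread = NULL, n_iter = n_iter, fit_frac = fit_frac,
                       redraws = rc_res$redraws, seed = seed),
                  class = "skill_report")
  pers <- do.call(rbind, lapply(persistence_lags, function(l) {
    pf <- persistence_forecast(observed, l)
    obs <- value_at(observed, pf$year)
    ok <- !is.na(obs) & !is.na(pf$fit)
    data.frame(lag = l,
               r = anomaly_correlation(obs[ok], pf$fit[ok]),
               beta = brier_score(obs[ok], pf$fit[ok]),
               n = sum(ok))
  }))
  structure(list(model = model, rc = rc, persistence = pers),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> model:\n")
  print(x$model)
  cat(" random chance (prediction period): median r = ",
      sprintf("%.3f", stats::median(x$rc$values$r_pred)), "\n", sep = "")
  cat(" persistence:\n")
  print(x$persistence, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Sub-sampled correlation skill of an external forecast
#'
#' Evaluates an externally supplied forecast series (e.g. short-term
#' assessment-based predictions) against observations by correlating on
#' `n` random `frac` subsamples of the paired years, returning the median
#' and inter-quartile range of `r`.
#'
#' @param observed observed [annual_series].
#' @param external_forecast forecast [annual_series] on overlapping years.
#' @param frac subsample fraction (default 0.8).
#' @param n number of subsamples (default 1000).
#' @param seed integer seed or `NULL`.
#' @return list with `r_median`, `r_q25`, `r_q75`, `r_full` (full-sample
#'   correlation) and the vector `r_values`.
#' @export
subsample_skill <- function(observed, external_forecast, frac = 0.8,
                            n = 1000L, seed = NULL) {
  stopifnot(inherits(observed, "annual_series"),
            inherits(external_forecast, "annual_series"))
  yrs <- intersect(observed$years, external_forecast$years)
  o <- value_at(observed, yrs)
  f <- value_at(external_forecast, yrs)
  ok <- !is.na(o) & !is.na(f)
  o <- o[ok]
  f <- f[ok]
  m <- length(o)
  if (m < 15L) stopf("subsample_skill needs >= 15 paired years, got %d", m)
  k <- max(3L, round(frac * m))
  r_values <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      idx <- sample.int(m, k)
      if (stats::var(o[idx]) == 0 || stats::var(f[idx]) == 0) {
        return(NA_real_)
      }
      stats::cor(o[idx], f[idx])
    }, numeric(1L))
  })
  r_values <- r_values[!is.na(r_values)]
  q <- stats::quantile(r_values, c(0.25, 0.5, 0.75), names = FALSE)
  list(r_median = q[2L], r_q25 = q[1L], r_q75 = q[3L],
       r_full = stats::cor(o, f), r_values = r_values)
}

#' Export a skill report as a tabular summary
#'
#' One row per metric and period with median and quartiles; benchmark
#' columns are appended when a `benchmark_report` is given.
#'
#' @param report a `skill_report` or `benchmark_report`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_skill <- function(report, path) {
  if (inherits(report, "benchmark_report")) {
    tab <- report$model$metrics
    tab$source <- "model"
    rc <- report$rc$metrics
    rc$source <- "random_chance"
    tab <- rbind(tab, rc)
  } else {
    stopifnot(inherits(report, "skill_report"))
    tab <- report$metrics
    tab$source <- "model"
  }
  for (col in c("median", "q25", "q75")) tab[[col]] <- format_num(tab[[col]])
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
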