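#' Fit the lag-l multiple linear regression model
#'
#' Ordinary least squares for `y_i = a0 + sum_n a_n x_{i-l,n} + e_i` on an
#' aligned design. The residual standard deviation uses the `n - p - 1`
#' denominator. A rank-deficient design is an error directing the caller to
#' [orthogonalize_predictors()] or to drop predictors.
#'
#' @param design an [align()] result with at least `p + 10` rows.
#' @return an object of class `lag_lm`: coefficients (intercept first),
#'   residual SD, training years, fitted values, residuals, the inverse
#'   cross-product matrix used for prediction intervals, a condition-number
#'   summary of the predictor block, and the `orthogonalized` flag.
#' @export
fit_model <- function(design) {
  stopifnot(inherits(design, "aligned_design"))
  p <- ncol(design$X)
  n <- length(design$y)
  if (n < p + 10L) {
    stopf("fit_model: %d rows for %d predictors; need at least %d",
          n, p, p + 10L)
  }
  X <- cbind("(Intercept)" = 1, design$X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stopf(paste("fit_model: rank-deficient design (collinear predictors);",
                "orthogonalize_predictors() or drop predictors"))
  }
  coefs <- qr.coef(qx, design$y)
  fitted <- drop(X %*% coefs)
  resid <- design$y - fitted
  df <- n - p - 1L
  sigma <- sqrt(sum(resid^2) / df)
  R <- qr.R(qx)
  xtx_inv <- chol2inv(R)
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  cond <- if (p > 1L) kappa(stats::cor(design$X), exact = TRUE) else 1
  structure(list(predictand = design$predictand,
                 predictors = design$predictors,
                 leads = design$leads,
                 coefficients = coefs,
                 sigma = sigma,
                 df = df,
                 years = design$years,
                 fitted = fitted,
                 residuals = resid,
                 xtx_inv = xtx_inv,
                 condition = cond,
                 orthogonalized = isTRUE(attr(design, "orthogonalized"))),
            class = "lag_lm")
}

#' @export
print.lag_lm <- function(x, ...) {
  cat(sprintf("<lag_lm> %s ~ %s\n", x$predictand,
              paste(sprintf("%s(lead %d)", x$predictors, x$leads),
                    collapse = " + ")))
  print(round(x$coefficients, 4))
  cat(sprintf("  residual SD %.4g on %d df; training %d-%d%s\n", x$sigma,
              x$df, x$years[1L], x$years[length(x$years)],
              if (x$orthogonalized) "; orthogonalized predictors" else ""))
  invisible(x)
}

#' Remove linear dependence among predictors by successive residualization
#'
#' Predictor `k` is replaced by its residual after OLS (with intercept) on
#' predictors `1..k-1`, in the listed order, so the resulting columns are
#' mutually uncorrelated and multicollinearity cannot influence the fitted
#' model. Residualization is order-dependent: the first predictor keeps its
#' raw variance, later ones keep only what earlier ones cannot explain. The
#' column span is unchanged, so fitted values and residuals of a subsequent
#' OLS are identical to the un-orthogonalized fit.
#'
#' @param design an [align()] result with at least two predictors.
#' @return the design with orthogonalized columns; near-zero residual
#'   columns are reported in attribute `degenerate`.
#' @export
orthogonalize_predictors <- function(design) {
  stopifnot(inherits(design, "aligned_design"))
  p <- ncol(design$X)
  if (p < 2L) stopf("orthogonalize_predictors needs >= 2 predictors")
  X <- design$X
  degenerate <- character()
  for (k in 2L:p) {
    Z <- cbind(1, X[, seq_len(k - 1L), drop = FALSE])
    fit <- stats::lm.fit(Z, X[, k])
    X[, k] <- fit$residuals
    if (stats::sd(X[, k]) < 1e-10) degenerate <- c(degenerate,
                                                   colnames(X)[k])
  }
  out <- design
  out$X <- X
  attr(out, "orthogonalized") <- TRUE
  attr(out, "degenerate") <- degenerate
  out
}

#' Durbin-Watson statistic of a residual sequence
#'
#' `DW = sum (e_t - e_{t-1})^2 / sum e_t^2` over residuals ordered by year.
#' If the years have gaps, successive differences are only taken within
#' runs of consecutive years; the denominator uses all residuals.
#' Approximately `2 (1 - rho1)` for lag-1 residual autocorrelation `rho1`.
#'
#' @param residuals numeric residuals.
#' @param years optional calendar years (defaults to a consecutive run).
#' @return list with `dw` and `gaps` (were year gaps present?).
#' @export
durbin_watson <- function(residuals, years = NULL) {
  e <- as.double(residuals)
  n <- length(e)
  if (n < 3L) stopf("durbin_watson needs at least 3 residuals")
  if (is.null(years)) years <- seq_len(n)
  o <- order(years)
  e <- e[o]
  years <- years[o]
  consec <- diff(years) == 1L
  num <- sum(diff(e)[consec]^2)
  list(dw = num / sum(e^2), gaps = !all(consec))
}

#' Residual diagnostics for a fitted lag-l model
#'
#' Checks the validity assumptions of the regression: residual independence
#' (Durbin-Watson statistic and the significance of the lag-1 residual
#' autocorrelation), normality (Shapiro-Wilk) and homoscedasticity
#' (correlation of absolute residuals with fitted values). Flags are set at
#' level `alpha`; a failed flag is a caveat, not an abort - short
#' environmental records routinely show residual autocorrelation that
#' cross-validation then has to guard against.
#'
#' @param model a [fit_model()] result with >= 15 training residuals.
#' @param alpha level for the pass/fail flags.
#' @return a `diagnostics_report` list: `dw`, `resid_ac1`, `ac1_p`,
#'   `shapiro_stat`, `shapiro_p`, `homosked_r`, `homosked_p`, logical
#'   `flags` (`independent`, `normal`, `homoscedastic`) and `gaps`.
#' @export
diagnose <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "lag_lm"))
  e <- model$residuals
  if (length(e) < 15L) stopf("diagnose needs >= 15 training residuals")
  dw <- durbin_watson(e, model$years)
  consec <- which(diff(model$years) == 1L)
  ac1 <- stats::cor(e[consec], e[consec + 1L])
  ac1_test <- stats::cor.test(e[consec], e[consec + 1L])
  sh <- stats::shapiro.test(if (length(e) > 5000L) e[seq_len(5000L)] else e)
  hm <- stats::cor.test(abs(e), model$fitted)
  structure(list(dw = dw$dw,
                 resid_ac1 = ac1,
                 ac1_p = ac1_test$p.value,
                 shapiro_stat = unname(sh$statistic),
                 shapiro_p = sh$p.value,
                 homosked_r = unname(hm$estimate),
                 homosked_p = hm$p.value,
                 flags = c(independent = ac1_test$p.value > alpha,
                           normal = sh$p.value > alpha,
                           homoscedastic = hm$p.value > alpha),
                 gaps = dw$gaps,
                 alpha = alpha),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("<diagnostics_report>\n")
  cat(sprintf("  Durbin-Watson %.3f (residual lag-1 r = %.3f, p = %.3g)%s\n",
              x$dw, x$resid_ac1, x$ac1_p,
              if (x$gaps) " [year gaps: DW over consecutive runs]" else ""))
  cat(sprintf("  Shapiro-Wilk W = %.3f (p = %.3g); |resid| vs fitted r = %.3f (p = %.3g)\n",
              x$shapiro_stat, x$shapiro_p, x$homosked_r, x$homosked_p))
  cat(sprintf("  flags at alpha=%.2g: independent=%s normal=%s homoscedastic=%s\n",
              x$alpha, x$flags[["independent"]], x$flags[["normal"]],
              x$flags[["homoscedastic"]]))
  invisible(x)
}

#' Forecast from a fitted lag-l model
#'
#' Point prediction `a0 + sum_n a_n x_{year-l,n}` for every requested
#' target year whose lagged predictors exist. Because every predictor leads
#' by `l` years, target years up to (last predictor year + l) are
#' predictable; years beyond the last training year are flagged `future`.
#' The 95% prediction interval uses the standard OLS predictive variance
#' `sigma^2 (1 + x0' (X'X)^{-1} x0)` with a two-sided t quantile
#' (`interval = "prediction"`), or the parameter-uncertainty term alone
#' (`interval = "parameter"`).
#'
#' @param object a [fit_model()] result.
#' @param predictors named list of [annual_series] covering the model's
#'   predictors.
#' @param years target years; default all predictable years.
#' @param interval `"prediction"`, `"parameter"` or `"none"`.
#' @param level interval coverage (default 0.95).
#' @param ... unused.
#' @return a `stock_forecast` data frame: `year`, `fit`, `lwr`, `upr`,
#'   `future`; attribute `provenance` records the model.
#' @export
predict.lag_lm <- function(object, predictors, years = NULL,
                           interval = c("prediction", "parameter", "none"),
                           level = 0.95, ...) {
  interval <- match.arg(interval)
  if (inherits(predictors, "annual_series")) predictors <- list(predictors)
  nm <- names(predictors)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- vapply(predictors, function(s) s$name, character(1L))
    names(predictors) <- nm
  }
  missing_pred <- setdiff(object$predictors, nm)
  if (length(missing_pred)) {
    stopf("predict: missing predictor series: %s",
          paste(missing_pred, collapse = ", "))
  }
  if (is.null(years)) {
    last <- min(vapply(object$predictors, function(p) {
      s <- predictors[[p]]
      s$years[length(s$years)] + object$leads[[p]]
    }, numeric(1L)))
    first <- max(vapply(object$predictors, function(p) {
      predictors[[p]]$years[1L] + object$leads[[p]]
    }, numeric(1L)))
    years <- seq.int(first, last)
  }
  years <- as.integer(years)
  X0 <- cbind(1, vapply(object$predictors, function(p) {
    value_at(predictors[[p]], years - object$leads[[p]])
  }, numeric(length(years))))
  if (length(years) == 1L) X0 <- matrix(X0, 1L)
  ok <- rowSums(is.na(X0)) == 0L
  if (!all(ok)) {
    message(sprintf("predict: %d target year(s) dropped for missing lagged predictors",
                    sum(!ok)))
  }
  years <- years[ok]
  X0 <- X0[ok, , drop = FALSE]
  fit <- drop(X0 %*% object$coefficients)
  half <- rep(NA_real_, length(fit))
  if (interval != "none") {
    leverage <- rowSums((X0 %*% object$xtx_inv) * X0)
    se <- if (interval == "prediction") {
      object$sigma * sqrt(1 + leverage)
    } else {
      object$sigma * sqrt(leverage)
    }
    half <- stats::qt(1 - (1 - level) / 2, df = object$df) * se
  }
  out <- data.frame(year = years, fit = fit,
                    lwr = fit - half, upr = fit + half,
                    future = years > object$years[length(object$years)])
  structure(out, class = c("stock_forecast", "data.frame"),
            provenance = sprintf("lag_lm:%s~%s(lead %s)", object$predictand,
                                 paste(object$predictors, collapse = "+"),
                                 paste(unique(object$leads), collapse = ",")),
            level = level, interval = interval)
}

#' @export
print.stock_forecast <- function(x, ...) {
  cat(sprintf("<stock_forecast> %s (%d years, %d future)\n",
              attr(x, "provenance"), nrow(x), sum(x$future)))
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE,
                   digits = 3)
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Lagged persistence forecast
#'
#' The no-skill dynamical benchmark: the forecast for year `i` is the
#' observed value in year `i - l`. Extends `l` years past the end of the
#' observations (those years are flagged `future`); no interval is
#' attached.
#'
#' @param observed an [annual_series].
#' @param lag_l forecast lag in years (>= 1).
#' @return a `stock_forecast` with provenance `"LP<lag>"`.
#' @export
persistence_forecast <- function(observed, lag_l) {
  stopifnot(inherits(observed, "annual_series"))
  lag_l <- as.integer(lag_l)
  if (lag_l < 1L) stopf("persistence lag must be >= 1")
  yrs <- seq.int(observed$years[1L] + lag_l,
                 observed$years[length(observed$years)] + lag_l)
  fit <- value_at(observed, yrs - lag_l)
  keep <- !is.na(fit)
  out <- data.frame(year = yrs[keep], fit = fit[keep],
                    lwr = NA_real_, upr = NA_real_,
                    future = yrs[keep] > observed$years[length(observed$years)])
  structure(out, class = c("stock_forecast", "data.frame"),
            provenance = sprintf("LP%d", lag_l), level = NA_real_,
            interval = "none")
}

#' Random-chance null model
#'
#' Fits the regression after independently permuting each predictor column
#' across rows (the predictand untouched), suppressing any real
#' predictor-predictand relationship. The resulting skill distribution
#' estimates what the modelling protocol can achieve by chance alone.
#'
#' @param design an [align()] result.
#' @param seed integer seed or `NULL`.
#' @return a `lag_lm` fitted to the shuffled design.
#' @export
random_chance_model <- function(design, seed = NULL) {
  stopifnot(inherits(design, "aligned_design"))
  with_seed(seed, fit_model(shuffle_design(design)))
}

shuffle_design <- function(design) {
  out <- design
  n <- nrow(design$X)
  for (k in seq_len(ncol(design$X))) {
    out$X[, k] <- design$X[sample.int(n), k]
  }
  out
}

#' Export a forecast as CSV
#'
#' Columns `year, fit, lwr, upr, spread_lwr, spread_upr, future,
#' provenance`; the spread columns are filled when a cross-validation
#' ensemble envelope has been attached (see [run_prediction()]).
#'
#' @param forecast a `stock_forecast`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_forecast <- function(forecast, path) {
  stopifnot(inherits(forecast, "stock_forecast"))
  df <- as.data.frame(forecast)
  for (col in c("lwr", "upr", "spread_lwr", "spread_upr")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- format_num(df[[col]])
  }
  df$fit <- format_num(df$fit)
  df$provenance <- attr(forecast, "provenance")
  df <- df[, c("year", "fit", "lwr", "upr", "spread_lwr", "spread_upr",
               "future", "provenance")]
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
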