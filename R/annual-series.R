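#' Annual scalar time series
#'
#' The universal currency of the pipeline: a named scalar time series on
#' consecutive calendar years. Gaps in the input years are densified to
#' explicit missing values so that calendar alignment is always preserved;
#' no operation in the package ever relabels a year.
#'
#' @param years integer calendar years (any order; gaps allowed).
#' @param values numeric values, `NA` for missing.
#' @param name series identifier (e.g. `"TSB"`, `"AMO"`).
#' @param units free-text units (e.g. `"1000 t"`, `"degC"`); empty by default.
#' @return an object of class `annual_series` with fields `name`, `units`,
#'   `years` (consecutive integers) and `values`.
#' @examples
#' s <- annual_series(c(1950, 1952), c(1.2, 3.4))
#' s$years   # 1950 1951 1952, with 1951 missing
#' @export
annual_series <- function(years, values, name = "series", units = "") {
  if (length(years) != length(values)) {
    stopf("years and values differ in length (%d vs %d)",
          length(years), length(values))
  }
  yi <- suppressWarnings(as.integer(years))
  if (anyNA(yi)) stopf("non-integer year labels in series '%s'", name)
  if (anyDuplicated(yi)) {
    stopf("duplicated year %d in series '%s'", yi[duplicated(yi)][1L], name)
  }
  o <- order(yi)
  yi <- yi[o]
  v <- as.double(values)[o]
  full <- seq.int(yi[1L], yi[length(yi)])
  dense <- rep(NA_real_, length(full))
  dense[match(yi, full)] <- v
  if (sum(!is.na(dense)) < 2L) {
    stopf("series '%s' needs at least 2 non-missing values", name)
  }
  structure(list(name = as.character(name), units = as.character(units),
                 years = full, values = dense),
            class = "annual_series")
}

#' @export
print.annual_series <- function(x, ...) {
  n_ok <- sum(!is.na(x$values))
  cat(sprintf("<annual_series> %s%s: %d-%d (%d years, %d observed)\n",
              x$name, if (nzchar(x$units)) paste0(" [", x$units, "]") else "",
              x$years[1L], x$years[length(x$years)], length(x$years), n_ok))
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(year = x$years, value = x$values)
}

#' @export
length.annual_series <- function(x) length(x$years)

#' Look up series values at given calendar years
#'
#' Years outside the series span yield `NA`.
#'
#' @param series an [annual_series].
#' @param years integer years.
#' @return numeric vector aligned with `years`.
#' @export
value_at <- function(series, years) {
  idx <- match(as.integer(years), series$years)
  out <- rep(NA_real_, length(years))
  ok <- !is.na(idx)
  out[ok] <- series$values[idx[ok]]
  out
}

#' Read an annual series from a two-column CSV file
#'
#' Expects one header line and two columns, year and value; missing values
#' are empty fields. Non-consecutive years are densified with missing
#' values. Duplicated or unparseable year labels are format errors naming
#' the offending line.
#'
#' @param path file path.
#' @param name series name; defaults to the file name without extension.
#' @param units units string attached to the result.
#' @return an [annual_series].
#' @export
read_series <- function(path, name = NULL, units = "") {
  if (!file.exists(path)) stopf("series file not found: %s", path)
  raw <- utils::read.csv(path, header = TRUE, colClasses = "character",
                         strip.white = TRUE)
  if (ncol(raw) < 2L) stopf("%s: expected two columns (year,value)", path)
  yr <- suppressWarnings(as.integer(raw[[1L]]))
  if (anyNA(yr)) {
    bad <- which(is.na(yr))[1L]
    stopf("%s: unparseable year '%s' on data line %d", path, raw[bad, 1L], bad)
  }
  if (anyDuplicated(yr)) {
    stopf("%s: duplicated year %d", path, yr[duplicated(yr)][1L])
  }
  vv <- raw[[2L]]
  vv[!nzchar(vv)] <- NA_character_
  val <- suppressWarnings(as.double(vv))
  if (any(!is.na(vv) & is.na(val))) {
    bad <- which(!is.na(vv) & is.na(val))[1L]
    stopf("%s: unparseable value '%s' on data line %d", path, vv[bad], bad)
  }
  annual_series(yr, val,
                name = name %||% sub("\\.[^.]*$", "", basename(path)),
                units = units)
}

#' Write an annual series to a two-column CSV file
#'
#' Missing values are written as empty fields; `read_series()` round-trips
#' the years and values exactly.
#'
#' @param series an [annual_series].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "annual_series"))
  df <- data.frame(year = series$years,
                   value = format_num(series$values))
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

# Locale/option-independent numeric formatting for deterministic files;
# 17 significant digits round-trip doubles exactly.
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1L))
}

#' Anomalies relative to a fixed baseline window
#'
#' Subtracts the mean over the non-missing years of the baseline window
#' (defaults to 1950-2012, the reference period used throughout the
#' package's examples). Units are preserved.
#'
#' @param series an [annual_series].
#' @param baseline_start,baseline_end first and last baseline year. `NULL`
#'   means the series' own full span.
#' @param min_overlap minimum number of non-missing baseline years.
#' @return an [annual_series] of anomalies.
#' @export
to_anomalies <- function(series, baseline_start = 1950, baseline_end = 2012,
                         min_overlap = 10L) {
  stopifnot(inherits(series, "annual_series"))
  b0 <- baseline_start %||% series$years[1L]
  b1 <- baseline_end %||% series$years[length(series$years)]
  inside <- series$years >= b0 & series$years <= b1
  base <- series$values[inside]
  n_base <- sum(!is.na(base))
  if (n_base < min_overlap) {
    stopf("baseline %d-%d overlaps series '%s' by only %d non-missing years (need %d)",
          b0, b1, series$name, n_base, min_overlap)
  }
  out <- series
  out$values <- series$values - mean(base, na.rm = TRUE)
  out
}

#' Remove an ordinary least-squares linear trend
#'
#' Fits value ~ year over the non-missing pairs and returns the residual
#' series; missing years stay missing. Idempotent up to rounding.
#'
#' @param series an [annual_series].
#' @return detrended [annual_series].
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "annual_series"))
  ok <- !is.na(series$values)
  if (sum(ok) < 3L) stopf("detrend_linear: series '%s' has fewer than 3 values",
                          series$name)
  yr <- series$years
  cf <- stats::coef(stats::lm.fit(cbind(1, yr[ok]), series$values[ok]))
  out <- series
  out$values <- series$values - (cf[1L] + cf[2L] * yr)
  out
}

# Centered running mean; even widths use half-weighted end points so the
# window stays symmetric. Edges shrink to the available window.
running_mean <- function(v, width) {
  if (width %% 2L == 1L) {
    w <- rep(1, width)
  } else {
    w <- c(0.5, rep(1, width - 1L), 0.5)
  }
  half <- (length(w) - 1L) %/% 2L
  n <- length(v)
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    off <- max(1L, t - half):min(n, t + half)
    wt <- w[off - t + half + 1L]
    x <- v[off]
    keep <- !is.na(x)
    if (any(keep)) out[t] <- sum(wt[keep] * x[keep]) / sum(wt[keep])
  }
  out
}

#' Low-pass filter: centered running mean
#'
#' @param series an [annual_series].
#' @param cutoff_years window width in years (default 5).
#' @return smoothed [annual_series].
#' @seealso [highpass()] for the exact complement.
#' @export
lowpass <- function(series, cutoff_years = 5) {
  stopifnot(inherits(series, "annual_series"))
  if (cutoff_years < 2) stopf("cutoff_years must be >= 2")
  if (length(series$years) < cutoff_years) {
    stopf("series '%s' shorter than the cut-off window", series$name)
  }
  out <- series
  lp <- running_mean(series$values, as.integer(cutoff_years))
  lp[is.na(series$values)] <- NA_real_
  out$values <- lp
  out
}

#' High-pass filter: series minus its centered running mean
#'
#' `highpass(s, w)$values + lowpass(s, w)$values` reconstructs the original
#' values exactly, so the decomposition is exactly complementary.
#'
#' @inheritParams lowpass
#' @return filtered [annual_series].
#' @export
highpass <- function(series, cutoff_years = 5) {
  lp <- lowpass(series, cutoff_years)
  out <- series
  out$values <- series$values - lp$values
  out
}

#' Harvest rate: annual catch divided by total stock biomass
#'
#' Computed on the year intersection of the two series; a non-positive
#' biomass in any overlapping year is a domain error. The result is
#' dimensionless.
#'
#' @param catch annual catch, an [annual_series].
#' @param tsb total stock biomass, an [annual_series] in the same units.
#' @return an [annual_series] named `"harvest_rate"`.
#' @export
harvest_rate <- function(catch, tsb) {
  stopifnot(inherits(catch, "annual_series"), inherits(tsb, "annual_series"))
  yrs <- intersect(catch$years, tsb$years)
  if (length(yrs) < 2L) stopf("catch and TSB series do not overlap")
  c_v <- value_at(catch, yrs)
  b_v <- value_at(tsb, yrs)
  both <- !is.na(c_v) & !is.na(b_v)
  if (any(both & b_v <= 0)) {
    stopf("TSB is non-positive in year %d", yrs[which(both & b_v <= 0)[1L]])
  }
  annual_series(yrs, ifelse(both, c_v / b_v, NA_real_),
                name = "harvest_rate", units = "")
}
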