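#' Build a lag-aware regression design from annual series
#'
#' Assembles the design behind the lag-l regression
#' `y_i = a0 + sum_n a_n x_{i-l_n, n} + e_i`: for every predictand year `i`
#' the row holds each predictor at year `i - l_n`. Only years where the
#' predictand and every lagged predictor are non-missing are kept (listwise
#' deletion); shifting is pure lead bookkeeping, never index arithmetic on
#' compacted arrays, so calendar labels are preserved.
#'
#' @param predictand an [annual_series] (the `y`).
#' @param predictors a named list of [annual_series] (the `x`), or a single
#'   series.
#' @param leads non-negative integer lead(s) in years, recycled across
#'   predictors; lead `l` means the predictor value of year `i - l` explains
#'   year `i`.
#' @return an object of class `aligned_design` with fields `predictand`,
#'   `predictors`, `leads`, `years`, `y` and matrix `X` (one named column
#'   per predictor).
#' @examples
#' y <- annual_series(1950:2012, rnorm(63), "TSB")
#' x <- annual_series(1950:2012, rnorm(63), "AMO")
#' d <- align(y, list(AMO = x), leads = 7)
#' range(d$years)  # 1957 2012
#' @export
align <- function(predictand, predictors, leads) {
  stopifnot(inherits(predictand, "annual_series"))
  if (inherits(predictors, "annual_series")) predictors <- list(predictors)
  if (!length(predictors)) stopf("align: no predictors given")
  nm <- names(predictors)
  if (is.null(nm) || any(!nzchar(nm))) {
    nm <- vapply(predictors, function(s) s$name, character(1L))
  }
  if (anyDuplicated(nm)) stopf("align: duplicated predictor names")
  p <- length(predictors)
  leads <- as.integer(rep_len(leads, p))
  if (any(leads < 0L)) stopf("align: leads must be non-negative")

  yrs <- predictand$years
  y <- predictand$values
  X <- matrix(NA_real_, length(yrs), p, dimnames = list(NULL, nm))
  for (k in seq_len(p)) {
    X[, k] <- value_at(predictors[[k]], yrs - leads[k])
  }
  keep <- !is.na(y) & rowSums(is.na(X)) == 0L
  if (!any(keep)) {
    cov <- vapply(seq_len(p), function(k) {
      s <- predictors[[k]]
      sprintf("%s (lead %d): %d-%d", nm[k], leads[k],
              s$years[1L], s$years[length(s$years)])
    }, character(1L))
    stopf("align: no year has complete data. Predictand %s: %d-%d; %s",
          predictand$name, yrs[1L], yrs[length(yrs)],
          paste(cov, collapse = "; "))
  }
  structure(list(predictand = predictand$name,
                 predictors = nm,
                 leads = stats::setNames(leads, nm),
                 years = yrs[keep],
                 y = y[keep],
                 X = X[keep, , drop = FALSE]),
            class = "aligned_design")
}

#' @export
print.aligned_design <- function(x, ...) {
  cat(sprintf("<aligned_design> %s ~ %s\n", x$predictand,
              paste(sprintf("%s(lead %d)", x$predictors, x$leads),
                    collapse = " + ")))
  cat(sprintf("  %d complete rows, years %d-%d\n", length(x$y),
              x$years[1L], x$years[length(x$years)]))
  invisible(x)
}

#' Subset the rows of an aligned design
#'
#' @param design an [align()] result.
#' @param rows integer or logical row index.
#' @return an `aligned_design` on the selected rows.
#' @keywords internal
design_rows <- function(design, rows) {
  out <- design
  out$years <- design$years[rows]
  out$y <- design$y[rows]
  out$X <- design$X[rows, , drop = FALSE]
  out
}
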