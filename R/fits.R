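# Least-squares fits shared by the three stage models.

new_fit_result <- function(slope, intercept, r2, n, residuals) {
  structure(
    list(slope = slope, intercept = intercept, r2 = r2, n = n,
         residuals = residuals),
    class = "fate_fit"
  )
}

#' @export
print.fate_fit <- function(x, ...) {
  cat(sprintf("<fit: slope %.6g, intercept %.6g, r2 %.4f, n %d>\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

check_xy <- function(x, y, min_n) {
  if (!is.numeric(x) || !is.numeric(y)) {
    fate_abort("`x` and `y` must be numeric.", "input_error")
  }
  if (length(x) != length(y)) {
    fate_abort("`x` and `y` must have the same length.", "input_error")
  }
  if (length(x) < min_n) {
    fate_abort(sprintf("Need at least %d point(s).", min_n), "input_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    fate_abort("`x` and `y` must be finite (drop NA pairs first).",
               "input_error")
  }
}

#' Ordinary least-squares line
#'
#' Fits `y = intercept + slope * x` by OLS; `r2` is the squared Pearson
#' correlation of `x` and `y` (defined as 1 when `y` has zero variance, i.e.
#' a perfectly flat and perfectly fitted line).
#'
#' @param x,y Equal-length numeric vectors, `length >= 2`, with `x` not all
#'   identical.
#' @return A `fate_fit` with fields `slope`, `intercept`, `r2`, `n`,
#'   `residuals`.
#' @examples
#' fit_linear(c(1, 2, 3), c(2, 4, 6))
#' @export
fit_linear <- function(x, y) {
  check_xy(x, y, min_n = 2L)
  if (stats::var(x) == 0) {
    fate_abort("`x` has zero variance; a slope cannot be estimated.",
               "fit_error")
  }
  fm <- lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else stats::cor(x, y)^2
  new_fit_result(
    slope = unname(coef(fm)[["x"]]),
    intercept = unname(coef(fm)[["(Intercept)"]]),
    r2 = r2, n = length(x), residuals = unname(stats::residuals(fm))
  )
}

#' Least-squares line through the origin
#'
#' Fits `y = slope * x` with the closed form `slope = sum(x*y) / sum(x^2)`
#' (equivalently `lm(y ~ 0 + x)`). Because the model has no intercept, the
#' usual coefficient of determination is not well defined; for comparability
#' with intercept fits, `r2 = 1 - SSE / SST` with SST taken about the mean of
#' `y`, clamped to `[0, 1]` (when SST is 0, `r2` is 1 for a perfect fit and
#' 0 otherwise).
#'
#' @param x,y Equal-length numeric vectors, `length >= 1`, with
#'   `sum(x^2) > 0`.
#' @return A `fate_fit` (intercept fixed at 0).
#' @examples
#' fit_through_origin(c(1, 2, 4), c(3, 6, 12))
#' @export
fit_through_origin <- function(x, y) {
  check_xy(x, y, min_n = 1L)
  if (sum(x^2) == 0) {
    fate_abort("All `x` are zero; a through-origin slope cannot be estimated.",
               "fit_error")
  }
  fm <- lm(y ~ 0 + x)
  slope <- unname(coef(fm)[["x"]])
  res <- y - slope * x
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) {
    if (sse <= .Machine$double.eps^0.5) 1 else 0
  } else {
    min(max(1 - sse / sst, 0), 1)
  }
  new_fit_result(slope = slope, intercept = 0, r2 = r2, n = length(x),
                 residuals = res)
}
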