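#' Pearson correlation with two-tailed significance
#'
#' Product-moment correlation and the two-tailed p-value from the t
#' transform `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3; pairs with missing
#'   values are dropped.
#' @return list of class `correlation_result`: `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 3)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(r = r, p = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f, two-tailed p = %.4g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' Simple ordinary least squares fit
#'
#' Least-squares line of `y` on `x` via [stats::lm()], with R-squared, the
#' slope's two-tailed p-value, residuals in input row order, and the
#' Durbin-Watson statistic of those residuals. For a constant response
#' (zero total sum of squares) R-squared is reported as 0 by convention.
#'
#' @param y response; @param x single predictor, non-degenerate.
#' @return list of class `ols_fit`: `slope`, `intercept`, `r_squared`,
#'   `slope_p`, `residuals`, `durbin_watson`, `n`, and the underlying `lm`
#'   fit as `model`.
#' @export
ols_simple <- function(y, x) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x, na.rm = TRUE) == 0) stop("degenerate predictor")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  res <- stats::residuals(fit)
  r2 <- if (stats::var(y, na.rm = TRUE) == 0) 0 else sm$r.squared
  dw <- if (all(res == 0)) NA_real_ else durbin_watson(res)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 slope_p = unname(sm$coefficients[2, 4]),
                 residuals = unname(res),
                 durbin_watson = dw,
                 n = length(res),
                 model = fit),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("y = %.4f x + %.4f   (R2 = %.3f, slope p = %.4g, DW = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$slope_p,
              x$durbin_watson, x$n))
  invisible(x)
}

#' Durbin-Watson statistic
#'
#' `sum((e_t - e_(t-1))^2) / sum(e_t^2)` over residuals in their given
#' order; values near 2 indicate no first-order autocorrelation. The order
#' must be the meaningful record order (here, patch number) — re-sorting
#' changes the statistic.
#'
#' @param residuals ordered numeric vector, length >= 2, not all zero.
#' @return the statistic, in \[0, 4\].
#' @export
durbin_watson <- function(residuals) {
  stopifnot(length(residuals) >= 2, !anyNA(residuals))
  if (all(residuals == 0)) stop("all-zero residuals: statistic undefined")
  sum(diff(residuals)^2) / sum(residuals^2)
}

#' Backward stepwise elimination on coefficient p-values
#'
#' Fits the multiple linear model on all predictors and repeatedly removes
#' the predictor with the largest two-tailed p-value exceeding `alpha`,
#' refitting after each removal, until every remaining predictor is
#' significant (or none remains). This is the SPSS-style significance
#' criterion, not AIC. Alongside the final multiple fit, a simple
#' regression is reported for each retained predictor (the form in which
#' stepwise results are conventionally quoted in this literature).
#'
#' @param y response vector.
#' @param predictors named list (or data.frame) of predictor vectors.
#' @param alpha removal threshold on the coefficient p-value, default 0.05.
#' @return list of class `stepwise_result`: `retained` (names),
#'   `removed` (data.frame of name, p-value at removal, step), `final_model`
#'   (`lm` on the retained set, or NULL if none), and `simple_fits` (named
#'   list of [ols_simple()] fits for the retained predictors).
#' @export
backward_stepwise <- function(y, predictors, alpha = 0.05) {
  d <- as.data.frame(predictors)
  stopifnot(ncol(d) >= 1, nrow(d) == length(y))
  vars <- names(d)
  removed <- data.frame(predictor = character(), p_value = numeric(),
                        step = integer())
  step <- 0L
  repeat {
    if (!length(vars)) { fit <- NULL; break }
    fit <- stats::lm(stats::reformulate(vars, response = "y"),
                     data = cbind(y = y, d))
    pv <- summary(fit)$coefficients[-1, 4]
    names(pv) <- vars
    worst <- which.max(pv)
    if (pv[worst] <= alpha) break
    step <- step + 1L
    removed <- rbind(removed,
                     data.frame(predictor = vars[worst],
                                p_value = unname(pv[worst]), step = step))
    vars <- vars[-worst]
  }
  simple <- stats::setNames(
    lapply(vars, function(v) ols_simple(y, d[[v]])), vars)
  structure(list(retained = vars, removed = removed, final_model = fit,
                 simple_fits = simple),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("backward stepwise elimination\n")
  if (nrow(x$removed))
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("  step %d: removed %s (p = %.3f)\n", x$removed$step[i],
                  x$removed$predictor[i], x$removed$p_value[i]))
  else cat("  nothing removed\n")
  cat("  retained:", if (length(x$retained)) paste(x$retained, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
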