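# Temperature-compensation statistics: per-group period-temperature
# regression, the differential-slope test, and Q10 with error propagation.

#' Ordinary least-squares fit of an observable against temperature
#'
#' Fits `observable = intercept + slope * temperature` by OLS. Temperatures
#' are centered internally for numerical conditioning; the returned intercept
#' is on the original (uncentered) scale. The returned object carries the
#' sufficient statistics (centered sum of squares, residual sum of squares,
#' sample size) needed by [compare_slopes()] and [q10_from_fit()].
#'
#' @param temperature numeric vector of temperatures (degrees C).
#' @param observable numeric vector, same length (e.g. period in hours).
#' @return An object of class `temp_fit`: list with `slope_b`, `intercept`,
#'   `se_slope`, `n`, `x_center`, `y_center`, `sum_x2` (centered), `residual_ss`,
#'   `sigma2` (residual variance, df = n - 2), `fitted`, `residuals`.
#' @examples
#' f <- fit_temperature_line(c(32, 35, 39), c(24.4, 24.0, 23.5))
#' f$slope_b
#' @export
fit_temperature_line <- function(temperature, observable) {
  ok <- is.finite(temperature) & is.finite(observable)
  x <- temperature[ok]
  y <- observable[ok]
  n <- length(x)
  if (n < 3L)
    stop("fit_temperature_line: need at least 3 finite points, got ", n)
  if (length(unique(x)) < 2L)
    stop("fit_temperature_line: all temperatures identical; slope undefined")
  xbar <- mean(x)
  ybar <- mean(y)
  xc <- x - xbar
  sxx <- sum(xc^2)
  b <- sum(xc * (y - ybar)) / sxx
  fitted <- ybar + b * xc
  res <- y - fitted
  rss <- sum(res^2)
  sigma2 <- rss / (n - 2L)
  structure(list(
    slope_b = b,
    intercept = ybar - b * xbar,
    se_slope = sqrt(sigma2 / sxx),
    n = n,
    x_center = xbar,
    y_center = ybar,
    sum_x2 = sxx,
    residual_ss = rss,
    sigma2 = sigma2,
    fitted = fitted,
    residuals = res
  ), class = "temp_fit")
}

#' Predict from a temperature line
#'
#' @param object a `temp_fit` from [fit_temperature_line()].
#' @param newdata numeric vector of temperatures.
#' @param ... ignored.
#' @return numeric vector of predicted observables.
#' @export
predict.temp_fit <- function(object, newdata, ...) {
  object$y_center + object$slope_b * (newdata - object$x_center)
}

#' @export
print.temp_fit <- function(x, ...) {
  cat(sprintf("temperature line: slope %.4g +/- %.3g per degC, intercept %.4g, n = %d\n",
              x$slope_b, x$se_slope, x$intercept, x$n))
  invisible(x)
}

#' Test whether two regression slopes are identical
#'
#' Pooled-residual-variance t test for equality of two regression slopes
#' (the classical common-slope test): with per-group residual sums of squares
#' RSS1, RSS2 and centered sums of squares Sxx1, Sxx2,
#' \deqn{s^2 = (RSS_1 + RSS_2) / (n_1 + n_2 - 4),\quad
#'   t = (b_1 - b_2) / \sqrt{s^2/Sxx_1 + s^2/Sxx_2}}
#' with `n1 + n2 - 4` degrees of freedom and a two-sided p value.
#'
#' This is the test used to decide whether the free-running period (or any
#' other observable) responds differently to temperature in two genotypes.
#'
#' If both groups fit their lines exactly (zero pooled variance) the test is
#' degenerate: p = 1 when the slopes agree, p = 0 with `degenerate = TRUE`
#' when they differ.
#'
#' @param g1,g2 two-column data frames / matrices with columns
#'   `(temperature, observable)`, or lists with elements `temperature` and
#'   `observable`.
#' @return object of class `slope_test`: list with `b1`, `b2`, `se_diff`,
#'   `t_stat`, `df`, `p_value`, `degenerate`, and the two `temp_fit`s.
#' @examples
#' g1 <- cbind(c(32, 35, 37, 39), c(24.4, 24.1, 23.8, 23.5))
#' g2 <- cbind(c(32, 35, 37, 39), c(27.4, 26.1, 25.2, 24.2))
#' compare_slopes(g1, g2)
#' @export
compare_slopes <- function(g1, g2) {
  f1 <- fit_temperature_line(as_xy(g1)$x, as_xy(g1)$y)
  f2 <- fit_temperature_line(as_xy(g2)$x, as_xy(g2)$y)
  compare_slopes_fits(f1, f2)
}

# internal: the test from two temp_fit objects (reused by the genome-wide
# screen so every feature goes through the same arithmetic).
compare_slopes_fits <- function(f1, f2) {
  df <- f1$n + f2$n - 4L
  if (df <= 0L)
    stop("compare_slopes: nonpositive degrees of freedom (n1 + n2 - 4 <= 0)")
  s2 <- (f1$residual_ss + f2$residual_ss) / df
  se <- sqrt(s2 / f1$sum_x2 + s2 / f2$sum_x2)
  dslope <- f1$slope_b - f2$slope_b
  degenerate <- FALSE
  if (se == 0) {
    if (dslope == 0) {
      t_stat <- 0
      p <- 1
    } else {
      t_stat <- sign(dslope) * Inf
      p <- 0
      degenerate <- TRUE
    }
  } else {
    t_stat <- dslope / se
    p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  }
  structure(list(
    b1 = f1$slope_b, b2 = f2$slope_b,
    se_diff = se, t_stat = t_stat, df = df, p_value = p,
    degenerate = degenerate, fit1 = f1, fit2 = f2
  ), class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("differential-slope test: b1 = %.4g, b2 = %.4g, t = %.3g, df = %d, p = %.3g%s\n",
              x$b1, x$b2, x$t_stat, x$df, x$p_value,
              if (x$degenerate) " (degenerate: zero pooled variance)" else ""))
  invisible(x)
}

as_xy <- function(g) {
  if (is.list(g) && !is.null(g$temperature)) {
    list(x = g$temperature, y = g$observable)
  } else {
    g <- as.matrix(g)
    list(x = g[, 1L], y = g[, 2L])
  }
}

#' Q10 temperature coefficient from two free-running periods
#'
#' For circadian periods the temperature coefficient is defined as
#' \deqn{Q_{10} = (\tau_{low} / \tau_{high})^{10/\Delta T}}
#' where `tau_low`, `tau_high` are the periods at the lower and higher
#' temperature and `delta_T` their separation in degrees C. A clock whose
#' period shortens with warming (rate speeds up) has Q10 > 1; a perfectly
#' compensated clock has Q10 = 1.
#'
#' @param tau_low period (hours) at the lower temperature; must be > 0.
#' @param tau_high period (hours) at the higher temperature; must be > 0.
#' @param delta_T temperature separation in degrees C; must be > 0.
#' @param span reference span in degrees (default 10).
#' @return object of class `q10`: list with `value` and `se` (NA here; use
#'   [q10_from_fit()] for propagated uncertainty).
#' @examples
#' q10_from_periods(24.4, 23.5, 7)  # ~1.06, a compensated clock
#' q10_from_periods(27.4, 24.2, 7)  # ~1.19, decompensated
#' @export
q10_from_periods <- function(tau_low, tau_high, delta_T, span = 10) {
  if (!is.finite(tau_low) || !is.finite(tau_high) || tau_low <= 0 || tau_high <= 0)
    stop("q10_from_periods: periods must be positive and finite")
  if (!is.finite(delta_T) || delta_T <= 0)
    stop("q10_from_periods: delta_T must be positive")
  structure(list(value = (tau_low / tau_high)^(span / delta_T), se = NA_real_),
            class = "q10")
}

#' @export
print.q10 <- function(x, ...) {
  if (is.finite(x$se)) cat(sprintf("Q10 = %.4g +/- %.3g\n", x$value, x$se))
  else cat(sprintf("Q10 = %.4g\n", x$value))
  invisible(x)
}

#' Q10 from a fitted temperature line, with delta-method uncertainty
#'
#' Evaluates the fitted line at `T_low` and `T_high` and forms
#' `Q10 = (tau(T_low)/tau(T_high))^(span/(T_high - T_low))`. The standard
#' error is first-order (delta-method) propagation through the full 2x2
#' covariance of the two predicted values, including the slope-intercept
#' covariance: with centered predictors, Cov(tau_l, tau_h) =
#' sigma^2 (1/n + x_l x_h / Sxx) where x = T - mean(T).
#'
#' @param fit a `temp_fit` from [fit_temperature_line()].
#' @param T_low,T_high evaluation temperatures (degrees C), `T_low < T_high`.
#' @param span reference span in degrees (default 10).
#' @return object of class `q10` with `value`, `se`, `tau_low`, `tau_high`.
#' @export
q10_from_fit <- function(fit, T_low, T_high, span = 10) {
  stopifnot(inherits(fit, "temp_fit"))
  if (!(T_low < T_high)) stop("q10_from_fit: require T_low < T_high")
  dT <- T_high - T_low
  tl <- predict(fit, T_low)
  th <- predict(fit, T_high)
  if (tl <= 0 || th <= 0)
    stop("q10_from_fit: predicted value nonpositive within [T_low, T_high]")
  ex <- span / dT
  value <- (tl / th)^ex
  # covariance of the two predictions (centered parametrization: intercept
  # and slope estimates are uncorrelated)
  xl <- T_low - fit$x_center
  xh <- T_high - fit$x_center
  v_ll <- fit$sigma2 * (1 / fit$n + xl^2 / fit$sum_x2)
  v_hh <- fit$sigma2 * (1 / fit$n + xh^2 / fit$sum_x2)
  v_lh <- fit$sigma2 * (1 / fit$n + xl * xh / fit$sum_x2)
  # gradient of Q10 wrt (tau_l, tau_h)
  gl <- value * ex / tl
  gh <- -value * ex / th
  se <- sqrt(max(0, gl^2 * v_ll + gh^2 * v_hh + 2 * gl * gh * v_lh))
  structure(list(value = value, se = se, tau_low = tl, tau_high = th),
            class = "q10")
}
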