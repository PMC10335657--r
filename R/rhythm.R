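# Circadian parameter estimation from bioluminescence traces: moving-average
# detrending, multi-start damped-cosine fitting, and per-condition summaries
# with the fit-error QC filter.

#' Detrend a bioluminescence trace with a moving-average baseline
#'
#' The baseline trend is a centered moving average over `window_h` hours. At
#' the edges the window shrinks symmetrically (half-width limited by the
#' distance to the nearer edge) so no data are discarded. `mode = "ratio"`
#' returns `signal/trend - 1` (the relative oscillation around the baseline
#' magnitude, requires strictly positive signal); `mode = "subtract"` returns
#' `signal - trend`.
#'
#' @param trace `biolum_trace`.
#' @param window_h window length, hours; must be shorter than the recording.
#' @param mode "ratio" or "subtract".
#' @return detrended `biolum_trace` (same time grid).
#' @export
detrend <- function(trace, window_h = 24, mode = c("ratio", "subtract")) {
  stopifnot(inherits(trace, "biolum_trace"))
  mode <- match.arg(mode)
  t <- trace$time
  y <- trace$signal
  span <- t[length(t)] - t[1L]
  if (window_h >= span)
    stop("detrend: window (", window_h, " h) must be shorter than the trace span (",
         span, " h)")
  if (mode == "ratio" && any(y <= 0))
    stop("detrend: ratio mode requires strictly positive signal")
  half <- window_h / 2
  trend <- vapply(seq_along(t), function(i) {
    h <- min(half, t[i] - t[1L], t[length(t)] - t[i])
    mean(y[t >= t[i] - h & t <= t[i] + h])
  }, numeric(1))
  out <- if (mode == "ratio") y / trend - 1 else y - trend
  biolum_trace(t, out, trace$annotation)
}

#' Fit an exponentially damped cosine to a detrended trace
#'
#' Least-squares fit of `y(t) = A exp(-lambda t) cos(2 pi (t - phi) / tau)`.
#' For each trial period on `cfg$tau_grid` (and a small damping grid) the
#' amplitude and phase enter linearly through the basis
#' `exp(-lambda t) {cos, sin}(2 pi t / tau)` and are profiled out; the best
#' starting point is then refined by a bounded quasi-Newton search over
#' `(tau, lambda)`. The multi-start over periods matters because the SSE
#' surface is multimodal in the period.
#'
#' The fit error is the RMS residual normalized by `|A|` (or by the signal
#' RMS when the fitted amplitude is zero), so the QC threshold
#' `cfg$fit_error_max` is scale-free. The first `cfg$fit_skip_h` hours are
#' excluded as a post-synchronization transient, and the final
#' `cfg$fit_trim_end_h` hours are excluded because the shrinking-window
#' moving average suppresses the oscillation near the recording end. A fit
#' is `valid` when the optimizer converged, the period lies in \[16, 40\] h,
#' and the fit error is at most `cfg$fit_error_max`.
#'
#' @param trace detrended `biolum_trace`.
#' @param cfg `run_config`.
#' @return object of class `rhythm_fit`: list with `period_tau`,
#'   `rel_amplitude`, `damping`, `phase`, `fit_error`, `valid`, `n_points`,
#'   and the well `annotation`.
#' @export
fit_damped_cosine <- function(trace, cfg = run_config()) {
  stopifnot(inherits(trace, "biolum_trace"))
  tmax <- trace$time[length(trace$time)] - cfg$fit_trim_end_h
  keep <- trace$time >= trace$time[1L] + cfg$fit_skip_h & trace$time <= tmax
  t <- trace$time[keep]
  y <- trace$signal[keep]
  if (length(t) < 24L)
    stop("fit_damped_cosine: fewer than 24 samples after transient/edge removal")
  invalid <- function() structure(
    list(period_tau = NA_real_, rel_amplitude = NA_real_, damping = NA_real_,
         phase = NA_real_, fit_error = Inf, valid = FALSE,
         n_points = length(t), annotation = trace$annotation),
    class = "rhythm_fit")
  if (all(y == 0) || sd(y) == 0) return(invalid())

  t0 <- t - t[1L]  # fit on a local clock; phase reported on this origin
  sse_linfit <- function(tau, lambda) {
    w <- 2 * pi / tau
    e <- exp(-lambda * t0)
    X <- cbind(e * cos(w * t0), e * sin(w * t0))
    fit <- stats::lm.fit(X, y)
    list(sse = sum(fit$residuals^2), a = fit$coefficients[1L],
         b = fit$coefficients[2L])
  }
  # box constraints via penalty: Nelder-Mead is robust near the zero-residual
  # floor where gradient-based line searches abort
  penalized <- function(p) {
    if (p[1L] < 14 || p[1L] > 44 || p[2L] < 0 || p[2L] > 0.3) return(1e300)
    sse_linfit(p[1L], p[2L])$sse
  }
  grid <- expand.grid(tau = cfg$tau_grid, lambda = c(0.001, 0.005, 0.01, 0.02, 0.05))
  sses <- mapply(function(tau, l) sse_linfit(tau, l)$sse, grid$tau, grid$lambda)
  st <- grid[which.min(sses), ]
  opt <- optim(c(st$tau, st$lambda), penalized, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  tau <- opt$par[1L]
  lambda <- opt$par[2L]
  lf <- sse_linfit(tau, lambda)
  a <- lf$a; b <- lf$b
  if (!is.finite(a) || !is.finite(b)) return(invalid())
  A <- sqrt(a^2 + b^2)
  # a cos(wt) + b sin(wt) = A cos(w (t - phi))
  phase <- (atan2(b, a) / (2 * pi / tau)) %% tau
  rms_res <- sqrt(lf$sse / length(y))
  fit_error <- if (A > 0) rms_res / A else rms_res / sqrt(mean(y^2))
  converged <- opt$convergence == 0L
  valid <- converged && is.finite(fit_error) &&
    fit_error <= cfg$fit_error_max && tau >= 16 && tau <= 40
  structure(list(period_tau = tau, rel_amplitude = A, damping = lambda,
                 phase = phase, fit_error = fit_error, valid = valid,
                 n_points = length(t), annotation = trace$annotation),
            class = "rhythm_fit")
}

#' @export
print.rhythm_fit <- function(x, ...) {
  cat(sprintf("rhythm fit: tau = %.2f h, A = %.3g, lambda = %.3g /h, phase = %.2f h, error = %.3g [%s]\n",
              x$period_tau, x$rel_amplitude, x$damping, x$phase, x$fit_error,
              if (isTRUE(x$valid)) "valid" else "invalid"))
  invisible(x)
}

#' Fit every well of a plate
#'
#' Convenience wrapper: detrend each trace and fit the damped cosine,
#' returning one row per well.
#'
#' @param traces list of `biolum_trace` (see [read_plate_timeseries()]).
#' @param cfg `run_config`.
#' @param mode detrending mode, see [detrend()].
#' @return data.frame with columns `sample_id`, `genotype`, `temperature_C`,
#'   `replicate`, `period_tau_h`, `rel_amplitude`, `damping`, `phase_h`,
#'   `fit_error`, `valid`.
#' @export
fit_plate <- function(traces, cfg = run_config(), mode = "ratio") {
  rows <- lapply(names(traces), function(w) {
    tr <- traces[[w]]
    # a well that cannot be detrended or fitted (e.g. nonpositive signal in
    # ratio mode) is a QC failure, not a pipeline abort
    fit <- tryCatch(
      fit_damped_cosine(detrend(tr, cfg$detrend_window_h, mode), cfg),
      error = function(e) {
        ct_log("rhythm", "well %s failed: %s", w, conditionMessage(e))
        list(period_tau = NA_real_, rel_amplitude = NA_real_,
             damping = NA_real_, phase = NA_real_, fit_error = Inf,
             valid = FALSE)
      })
    ann <- tr$annotation
    data.frame(sample_id = w,
               genotype = if (!is.null(ann)) ann$genotype else NA_character_,
               temperature_C = if (!is.null(ann)) ann$temperature_C else NA_real_,
               replicate = if (!is.null(ann)) ann$replicate else NA_integer_,
               period_tau_h = fit$period_tau,
               rel_amplitude = fit$rel_amplitude,
               damping = fit$damping,
               phase_h = fit$phase,
               fit_error = fit$fit_error,
               valid = fit$valid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ct_log("rhythm", "%d wells in, %d valid fits out", nrow(out), sum(out$valid))
  out
}

#' Summarize rhythm fits per condition
#'
#' Invalid fits (fit error above threshold, or non-converged) are excluded
#' before averaging; `n` is the post-QC count. Conditions with zero valid
#' fits are kept as flagged rows (`n = 0`, NA mean), never dropped silently.
#'
#' @param fits data.frame from [fit_plate()] (or with the same columns).
#' @param by character vector of grouping columns
#'   (default genotype + temperature).
#' @return data.frame with group columns, `period_mean_h`, `period_sd_h`,
#'   `n`, and `flagged` (TRUE when no valid fit existed).
#' @export
summarize_wells <- function(fits, by = c("genotype", "temperature_C")) {
  if (!nrow(fits)) stop("summarize_wells: empty fit table")
  key <- interaction(fits[by], drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    g <- fits[key == k, , drop = FALSE]
    v <- g[g$valid, , drop = FALSE]
    out <- g[1L, by, drop = FALSE]
    out$period_mean_h <- if (nrow(v)) mean(v$period_tau_h) else NA_real_
    out$period_sd_h <- if (nrow(v) > 1L) sd(v$period_tau_h) else NA_real_
    out$n <- nrow(v)
    out$flagged <- nrow(v) == 0L
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ct_log("rhythm", "summary over %d conditions; %d flagged (no valid fits)",
         nrow(out), sum(out$flagged))
  out
}
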