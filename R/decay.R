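# mRNA half-life estimation from transcription-shutoff time courses:
# log-linear fitting and group comparison.

#' Fit an mRNA half-life from a transcription-shutoff time course
#'
#' OLS of `ln(value)` on time; the decay rate is `k = -slope` and the
#' half-life `ln 2 / k`. The fitting scale is the natural log (the base
#' cancels in the half-life). Nonpositive values are dropped with a logged
#' count; a nonpositive decay rate yields an infinite half-life with
#' `stable = TRUE` rather than an error. The t = 0 point is included and no
#' normalization to t0 is applied (the slope is translation-invariant in log
#' space).
#'
#' @param times numeric vector of chase times, hours.
#' @param values expression values; nonpositive entries are dropped.
#' @return object of class `decay_fit`: list with `rate_k` (1/h),
#'   `half_life` (hours, possibly Inf), `r2`, `n_points`, `stable`.
#' @examples
#' fit_half_life(c(0, 1, 2), c(1, 0.5, 0.25))$half_life  # exactly 1 h
#' @export
fit_half_life <- function(times, values) {
  if (length(times) != length(values))
    stop("fit_half_life: times and values lengths differ")
  ok <- is.finite(times) & is.finite(values) & values > 0
  dropped <- sum(is.finite(values) & values <= 0)
  if (dropped) ct_log("decay", "%d nonpositive value(s) dropped", dropped)
  if (sum(ok) < 3L)
    stop("fit_half_life: need at least 3 positive values, got ", sum(ok))
  t <- times[ok]
  ly <- log(values[ok])
  if (length(unique(t)) < 2L)
    stop("fit_half_life: all time points identical")
  xc <- t - mean(t)
  b <- sum(xc * (ly - mean(ly))) / sum(xc^2)
  fitted <- mean(ly) + b * xc
  ss_res <- sum((ly - fitted)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  k <- -b
  stable <- k <= 0
  structure(list(rate_k = k,
                 half_life = if (stable) Inf else log(2) / k,
                 r2 = r2, n_points = sum(ok), stable = stable),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay fit: k = %.4g /h, t1/2 = %.3g h, r2 = %.3f, n = %d%s\n",
              x$rate_k, x$half_life, x$r2, x$n_points,
              if (x$stable) " [stable: nonpositive decay rate]" else ""))
  invisible(x)
}

#' Compare half-lives between two groups of experiments
#'
#' Two-sample t test on experiment-level half-lives. Callers are expected to
#' average technical replicates into one half-life per experiment first (use
#' [decay_table_fits()] with `average_replicates = TRUE`); the reported `n`
#' are experiment counts, not well counts. Infinite half-lives (stable fits)
#' are excluded with a logged count.
#'
#' @param half_lives_a,half_lives_b numeric vectors of per-experiment
#'   half-lives, hours.
#' @return data.frame: `mean_a`, `mean_b`, `difference`, `n_a`, `n_b`, `p`.
#' @export
compare_half_lives <- function(half_lives_a, half_lives_b) {
  a <- half_lives_a[is.finite(half_lives_a)]
  b <- half_lives_b[is.finite(half_lives_b)]
  n_inf <- sum(!is.finite(half_lives_a)) + sum(!is.finite(half_lives_b))
  if (n_inf) ct_log("decay", "%d non-finite half-life value(s) excluded", n_inf)
  if (length(a) < 2L || length(b) < 2L)
    stop("compare_half_lives: need at least 2 finite half-lives per group")
  p <- if (sd(c(a - mean(a), b - mean(b))) == 0) {
    if (mean(a) == mean(b)) 1 else 0
  } else {
    t.test(a, b)$p.value
  }
  data.frame(mean_a = mean(a), mean_b = mean(b),
             difference = mean(b) - mean(a),
             n_a = length(a), n_b = length(b), p = p)
}

#' Per-gene/genotype half-life fits from a long-format decay table
#'
#' Input columns: `gene`, `genotype`, `experiment`, `replicate`, `time_h`,
#' `value`. With `average_replicates = TRUE` (the default), technical
#' replicates are averaged per time point within each experiment before
#' fitting, so each experiment contributes a single half-life.
#'
#' @param decay_df long-format data.frame.
#' @param average_replicates average technical replicates per time point
#'   before fitting.
#' @return data.frame: `gene`, `genotype`, `experiment`, `half_life_h`,
#'   `rate_k`, `r2`, `n_points`.
#' @export
decay_table_fits <- function(decay_df, average_replicates = TRUE) {
  need <- c("gene", "genotype", "experiment", "replicate", "time_h", "value")
  miss <- setdiff(need, names(decay_df))
  if (length(miss))
    stop("decay_table_fits: missing column(s): ", paste(miss, collapse = ", "))
  key <- interaction(decay_df$gene, decay_df$genotype, decay_df$experiment,
                     drop = TRUE)
  rows <- lapply(split(decay_df, key), function(g) {
    if (average_replicates) {
      agg <- stats::aggregate(value ~ time_h, data = g, FUN = mean)
      t <- agg$time_h; v <- agg$value
    } else {
      t <- g$time_h; v <- g$value
    }
    fit <- fit_half_life(t, v)
    data.frame(gene = g$gene[1L], genotype = g$genotype[1L],
               experiment = g$experiment[1L],
               half_life_h = fit$half_life, rate_k = fit$rate_k,
               r2 = fit$r2, n_points = fit$n_points,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ct_log("decay", "%d gene x genotype x experiment fits", nrow(out))
  out
}
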