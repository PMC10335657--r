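# Genome-scale statistics: two-group shift tests at fixed temperature,
# per-feature temperature-response regressions, the wild-type vs knockdown
# differential temperature-response screen with per-feature Q10, BH
# correction, and cross-layer Venn/Fisher integration.

#' Benjamini-Hochberg adjustment with NA propagation
#'
#' Step-up FDR adjustment computed over the non-NA entries only; NA entries
#' are preserved in place and do not count toward the family size. Output is
#' elementwise >= input, capped at 1, and equivariant under reordering.
#'
#' @param p numeric vector of p values in \[0, 1\], NA allowed.
#' @return adjusted p values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("bh_adjust: p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Split a feature table by genotype
#'
#' @param table `feature_table`.
#' @return named list of `feature_table`s, one per genotype
#'   (`control`, `knockdown`).
#' @export
split_by_genotype <- function(table) {
  lapply(setNames(GENOTYPES, GENOTYPES), function(g) {
    keep <- table$meta$genotype == g
    structure(list(values = table$values[, keep, drop = FALSE],
                   meta = table$meta[keep, , drop = FALSE],
                   layer = table$layer),
              class = "feature_table")
  })
}

# layer-appropriate analysis values: ncom as-is; transcripts as
# log2(size-factor-normalized counts + 1); proteins are already log2.
analysis_values <- function(table) {
  if (table$layer == "transcript") {
    log2(normalize_counts(table$values) + 1)
  } else {
    table$values
  }
}

#' Two-group shift test at a fixed temperature
#'
#' Per feature, a Welch two-sample t test comparing knockdown against control.
#' The effect reported is layer-specific: `mean(kd) - mean(wt)` of NCOM
#' values for the ncom layer (a negative shift means 3' UTR shortening), and
#' the mean log2 difference (log2 fold change) for transcript and protein
#' layers (transcripts on log2 size-factor-normalized counts with a
#' pseudocount of 1). P values are BH-adjusted within the tested family;
#' features with fewer than 2 finite values in either group yield NA rows
#' excluded from the family.
#'
#' @param table `feature_table`, typically restricted to one temperature.
#' @param temperature optional: restrict to this temperature first.
#' @return data.frame: `feature`, `effect`, `mean_control`, `mean_knockdown`,
#'   `p`, `padj`.
#' @export
shift_test <- function(table, temperature = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.null(temperature)) {
    keep <- table$meta$temperature_C == temperature
    if (!any(keep)) stop("shift_test: no samples at temperature ", temperature)
    table <- structure(list(values = table$values[, keep, drop = FALSE],
                            meta = table$meta[keep, , drop = FALSE],
                            layer = table$layer), class = "feature_table")
  }
  vals <- analysis_values(table)
  is_kd <- table$meta$genotype == "knockdown"
  if (!any(is_kd) || all(is_kd))
    stop("shift_test: need samples of both genotypes")
  res <- t(apply(vals, 1L, function(v) {
    a <- v[!is_kd]; a <- a[is.finite(a)]
    b <- v[is_kd]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    eff <- mean(b) - mean(a)
    p <- if (sd(c(a - mean(a), b - mean(b))) == 0) {
      if (eff == 0) 1 else 0
    } else {
      t.test(b, a)$p.value
    }
    c(eff, mean(a), mean(b), p)
  }))
  out <- data.frame(feature = rownames(vals),
                    effect = res[, 1L],
                    mean_control = res[, 2L],
                    mean_knockdown = res[, 3L],
                    p = res[, 4L],
                    stringsAsFactors = FALSE)
  out$padj <- bh_adjust(out$p)
  rownames(out) <- NULL
  ct_log("diffresponse", "shift test [%s]: %d features in, %d testable, %d at padj < 0.05",
         table$layer, nrow(out), sum(!is.na(out$p)),
         sum(out$padj < 0.05, na.rm = TRUE))
  out
}

#' Per-feature temperature-response regression within one genotype
#'
#' OLS of the (layer-appropriate) value against temperature per feature, with
#' the p value from the slope t statistic (df = n - 2) and BH adjustment
#' within the layer family. The reported effect is the fitted change across
#' the evaluation span: `slope * (temp_high - temp_low)` — a delta-NCOM for
#' the ncom layer and a log2 fold change for abundance layers.
#'
#' @param table `feature_table` restricted to one genotype.
#' @param cfg `run_config` (evaluation temperatures, FDR level).
#' @return data.frame: `feature`, `slope`, `intercept`, `se_slope`, `n`,
#'   `effect`, `p`, `padj`.
#' @export
temperature_response <- function(table, cfg = run_config()) {
  stopifnot(inherits(table, "feature_table"))
  if (length(unique(table$meta$genotype)) != 1L)
    stop("temperature_response: table must contain a single genotype")
  vals <- analysis_values(table)
  temps <- table$meta$temperature_C
  span <- cfg$temp_high - cfg$temp_low
  res <- t(apply(vals, 1L, function(v) {
    ok <- is.finite(v)
    if (sum(ok) < 3L || length(unique(temps[ok])) < 3L)
      return(rep(NA_real_, 6L))
    f <- fit_temperature_line(temps[ok], v[ok])
    t_stat <- f$slope_b / f$se_slope
    p <- if (is.finite(t_stat)) 2 * pt(abs(t_stat), df = f$n - 2L, lower.tail = FALSE)
         else if (f$residual_ss == 0 && f$slope_b != 0) 0 else NA_real_
    c(f$slope_b, f$intercept, f$se_slope, f$n, f$slope_b * span, p)
  }))
  out <- data.frame(feature = rownames(vals),
                    slope = res[, 1L], intercept = res[, 2L],
                    se_slope = res[, 3L], n = res[, 4L],
                    effect = res[, 5L], p = res[, 6L],
                    stringsAsFactors = FALSE)
  out$padj <- bh_adjust(out$p)
  rownames(out) <- NULL
  ct_log("diffresponse", "temperature response [%s]: %d features, %d at padj < %g",
         table$layer, nrow(out),
         sum(out$padj < cfg$fdr_level, na.rm = TRUE), cfg$fdr_level)
  out
}

#' Differential temperature-response screen (wild type vs knockdown)
#'
#' Per feature, fits the temperature line in each genotype, tests slope
#' equality with the pooled-variance differential-slope statistic
#' (see [compare_slopes()]), BH-adjusts within the layer, and converts each
#' genotype's fitted endpoint values into a Q10 temperature coefficient.
#'
#' Q10 conventions: for abundance layers, fitted log2 values at the
#' evaluation temperatures are exponentiated back to the natural scale and
#' `Q10 = (value_high / value_low)^(span / dT)` — the rate-like convention
#' (abundance rising with warmth gives Q10 > 1). NCOM values are used on
#' their own scale with the same rate-like convention. (For free-running
#' periods the reciprocal convention of [q10_from_periods()] applies; periods
#' are handled by the tempcomp module, not here.)
#'
#' @param wt,kd `feature_table`s of the two genotypes over the same feature
#'   universe.
#' @param cfg `run_config`.
#' @return data.frame: `feature`, `slope_wt`, `slope_kd`, `intercept_wt`,
#'   `intercept_kd`, `t_stat`, `df`, `p_diff`, `padj_diff`, `q10_wt`,
#'   `q10_kd`.
#' @export
differential_response <- function(wt, kd, cfg = run_config()) {
  stopifnot(inherits(wt, "feature_table"), inherits(kd, "feature_table"))
  if (!identical(rownames(wt$values), rownames(kd$values)))
    stop("differential_response: feature universes differ between genotypes")
  if (wt$layer != kd$layer)
    stop("differential_response: layers differ")
  layer <- wt$layer
  vw <- analysis_values(wt)
  vk <- analysis_values(kd)
  tw <- wt$meta$temperature_C
  tk <- kd$meta$temperature_C
  q10_span <- cfg$q10_reference_span

  one <- function(i) {
    okw <- is.finite(vw[i, ])
    okk <- is.finite(vk[i, ])
    if (sum(okw) < 3L || sum(okk) < 3L ||
        length(unique(tw[okw])) < 2L || length(unique(tk[okk])) < 2L)
      return(rep(NA_real_, 9L))
    fw <- fit_temperature_line(tw[okw], vw[i, okw])
    fk <- fit_temperature_line(tk[okk], vk[i, okk])
    st <- compare_slopes_fits(fw, fk)
    q10 <- function(f) {
      lo <- predict(f, cfg$temp_low)
      hi <- predict(f, cfg$temp_high)
      if (layer %in% c("transcript", "protein")) {
        (2^(hi - lo))^(q10_span / (cfg$temp_high - cfg$temp_low))
      } else {
        if (lo <= 0 || hi <= 0) return(NA_real_)
        (hi / lo)^(q10_span / (cfg$temp_high - cfg$temp_low))
      }
    }
    c(fw$slope_b, fk$slope_b, fw$intercept, fk$intercept,
      st$t_stat, st$df, st$p_value, q10(fw), q10(fk))
  }
  res <- t(vapply(seq_len(nrow(vw)), one, numeric(9L)))
  out <- data.frame(feature = rownames(vw),
                    slope_wt = res[, 1L], slope_kd = res[, 2L],
                    intercept_wt = res[, 3L], intercept_kd = res[, 4L],
                    t_stat = res[, 5L], df = res[, 6L], p_diff = res[, 7L],
                    q10_wt = res[, 8L], q10_kd = res[, 9L],
                    stringsAsFactors = FALSE)
  out$padj_diff <- bh_adjust(out$p_diff)
  rownames(out) <- NULL
  ct_log("diffresponse",
         "differential response [%s]: %d features, %d at padj < %g",
         layer, nrow(out), sum(out$padj_diff < cfg$fdr_level, na.rm = TRUE),
         cfg$fdr_level)
  out
}

#' Cross-layer overlap: Venn regions and pairwise Fisher enrichment
#'
#' Computes the count of every Venn region over the named significant sets
#' and, for each pair of sets, the 2x2 membership table over the universe,
#' its sample odds ratio `(a*d)/(b*c)`, and a two-sided Fisher's exact p.
#'
#' @param sig_sets named list of character vectors (feature ids), each a
#'   subset of `universe`.
#' @param universe character vector of all tested feature ids.
#' @return list with `venn` (data.frame `region`, `count`, one row per
#'   membership pattern including the all-out region) and `pairs`
#'   (data.frame `set_a`, `set_b`, `a`, `b`, `c`, `d`, `odds_ratio`, `p`).
#' @export
layer_overlap <- function(sig_sets, universe) {
  if (is.null(names(sig_sets)) || any(!nzchar(names(sig_sets))))
    stop("layer_overlap: sig_sets must be named")
  universe <- unique(universe)
  for (nm in names(sig_sets)) {
    out_of_univ <- setdiff(sig_sets[[nm]], universe)
    if (length(out_of_univ))
      stop("layer_overlap: set '", nm, "' has element(s) outside the universe: ",
           paste(head(out_of_univ, 5), collapse = ", "))
  }
  memb <- vapply(sig_sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (is.null(dim(memb))) memb <- matrix(memb, ncol = length(sig_sets))
  pattern <- apply(memb, 1L, function(r) paste(ifelse(r, names(sig_sets), ""),
                                               collapse = "&"))
  k <- length(sig_sets)
  all_patterns <- apply(expand.grid(rep(list(c(FALSE, TRUE)), k)), 1L,
                        function(r) paste(ifelse(r, names(sig_sets), ""),
                                          collapse = "&"))
  venn <- data.frame(region = all_patterns,
                     count = vapply(all_patterns,
                                    function(p) sum(pattern == p), 0L),
                     stringsAsFactors = FALSE)
  rownames(venn) <- NULL

  pairs <- NULL
  if (k >= 2L) {
    combos <- utils::combn(names(sig_sets), 2L)
    pairs <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
      na <- combos[1L, j]; nb <- combos[2L, j]
      ia <- memb[, na]; ib <- memb[, nb]
      a <- sum(ia & ib); b <- sum(ia & !ib)
      cc <- sum(!ia & ib); d <- sum(!ia & !ib)
      fr <- fisher_exact_p(a, b, cc, d)
      data.frame(set_a = na, set_b = nb, a = a, b = b, c = cc, d = d,
                 odds_ratio = if (b * cc > 0) (a * d) / (b * cc) else Inf,
                 p = fr, stringsAsFactors = FALSE)
    }))
  }
  list(venn = venn, pairs = pairs)
}

# two-sided Fisher's exact p for a 2x2 table given as counts
fisher_exact_p <- function(a, b, c, d) {
  fisher.test(matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE),
              alternative = "two.sided")$p.value
}
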