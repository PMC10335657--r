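# Genome-scale screen statistics: BH, shift tests, temperature response,
# differential response, cross-layer overlap.

test_that("BH adjustment matches the hand-computed step-up and preserves NA", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  p <- c(0.001, NA, 0.04, 0.5, NA, 0.012)
  adj <- bh_adjust(p)
  expect_true(all(is.na(adj[c(2, 5)])))
  # NA entries do not count toward the family: m = 4
  expect_equal(adj[!is.na(p)], p.adjust(p[!is.na(p)], "BH"))
  expect_true(all(adj >= p, na.rm = TRUE))
  # reordering equivariance
  set.seed(2)
  q <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(q)[perm], bh_adjust(q[perm]))
  # step-up formula oracle: cummin of sorted p * m / rank
  m <- length(q)
  o <- order(q, decreasing = TRUE)
  oracle <- pmin(1, cummin(q[o] * m / rank(q)[o]))[order(o)]
  expect_equal(bh_adjust(q), oracle, tolerance = 1e-12)
})

test_that("shift test: identical groups are null; shifted NCOM is detected", {
  # identical groups up to replicate labels -> effect 0, p = 1
  meta <- rbind(mk_meta(paste0("c", 1:3), "control", 37, layer = "protein"),
                mk_meta(paste0("k", 1:3), "knockdown", 37, layer = "protein"))
  v <- matrix(rep(c(20, 21, 22), 2), nrow = 1,
              dimnames = list("f1", meta$sample_id))
  sh <- shift_test(feature_table(v, meta, "protein"))
  expect_equal(sh$effect, 0)
  expect_equal(sh$p, 1, tolerance = 1e-12)

  # synthetic knockdown shift toward proximal usage: most interaction-free
  # shifted features flagged with negative deltaNCOM
  cfg <- synth_config(n_genes = 300, frac_interaction = 0, seed = 6)
  apa <- gen_apa_counts(cfg)
  nt <- ncom_table(apa$profiles, apa$utrs, apa$meta)
  sh2 <- shift_test(nt, temperature = 37)
  hit <- !is.na(sh2$padj) & sh2$padj < 0.05 & sh2$effect < 0
  expect_gt(mean(hit), 0.9)
})

test_that("features with too few finite values yield NA excluded from the family", {
  meta <- rbind(mk_meta(paste0("c", 1:3), "control", 37, layer = "protein"),
                mk_meta(paste0("k", 1:3), "knockdown", 37, layer = "protein"))
  set.seed(1)
  v <- matrix(rnorm(12, 20), 2, 6, dimnames = list(c("f1", "f2"), meta$sample_id))
  v["f2", c(1, 2)] <- NA  # one finite control value left
  sh <- shift_test(feature_table(v, meta, "protein"))
  expect_true(is.na(sh$p[sh$feature == "f2"]))
  expect_equal(sh$padj[sh$feature == "f1"], sh$p[sh$feature == "f1"])
})

test_that("temperature response: exact slopes, calibrated type-I, log2FC effect", {
  # exact linear feature, zero noise: slope recovered, p ~ 0
  meta <- mk_meta(sprintf("s%d", 1:9), "control",
                  rep(c(32, 37, 39), each = 3), rep(1:3, 3), layer = "protein")
  val <- 20 + 0.01 * (meta$temperature_C - 37)
  v <- matrix(val, 1, 9, dimnames = list("f1", meta$sample_id))
  tr <- temperature_response(feature_table(v, meta, "protein"))
  expect_equal(tr$slope, 0.01, tolerance = 1e-10)
  expect_lt(tr$p, 1e-12)
  expect_equal(tr$effect, 0.01 * 7, tolerance = 1e-10)

  # null features: fraction with p < 0.05 calibrated
  set.seed(10)
  v0 <- matrix(rnorm(1000 * 9, 20, 0.3), 1000, 9,
               dimnames = list(sprintf("f%04d", 1:1000), meta$sample_id))
  tr0 <- temperature_response(feature_table(v0, meta, "protein"))
  rate <- mean(tr0$p < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)

  # synthetic abundance with a known slope: fitted log2FC(32->39) ~ 0.7
  cfg <- synth_config(n_genes = 400, frac_interaction = 0,
                      abundance_temp_slope_log2 = 0.1,
                      abundance_temp_slope_sd_log2 = 0, seed = 12)
  ab <- gen_abundance(cfg, "protein")
  trs <- temperature_response(split_by_genotype(ab$table)$control)
  expect_equal(mean(trs$effect), 0.7, tolerance = 0.02)
})

test_that("differential response: self-comparison is null, flat features give Q10 = 1", {
  cfg <- synth_config(n_genes = 40, frac_interaction = 0, seed = 9)
  ab <- gen_abundance(cfg, "protein")
  wt <- split_by_genotype(ab$table)$control
  dr <- differential_response(wt, wt)
  expect_true(all(dr$p_diff == 1))
  expect_equal(dr$q10_wt, dr$q10_kd)

  # zero slope in both genotypes -> Q10 exactly 1 on every layer scale
  meta <- rbind(
    mk_meta(sprintf("c%d", 1:9), "control", rep(c(32, 37, 39), each = 3),
            rep(1:3, 3), layer = "protein"),
    mk_meta(sprintf("k%d", 1:9), "knockdown", rep(c(32, 37, 39), each = 3),
            rep(1:3, 3), layer = "protein"))
  v <- matrix(20, 1, 18, dimnames = list("f1", meta$sample_id))
  ftab <- feature_table(v, meta, "protein")
  h <- split_by_genotype(ftab)
  dr2 <- differential_response(h$control, h$knockdown)
  expect_equal(dr2$q10_wt, 1)
  expect_equal(dr2$q10_kd, 1)
})

test_that("differential response: genotype swap negates slope differences", {
  cfg <- synth_config(n_genes = 60, seed = 15)
  ab <- gen_abundance(cfg, "transcript")
  h <- split_by_genotype(ab$table)
  a <- differential_response(h$control, h$knockdown)
  b <- differential_response(h$knockdown, h$control)
  expect_equal(a$slope_wt - a$slope_kd, -(b$slope_wt - b$slope_kd),
               tolerance = 1e-10)
  expect_equal(a$p_diff, b$p_diff, tolerance = 1e-10)
})

test_that("differential response controls FDR under the generator's null", {
  hits <- vapply(1:20, function(s) {
    cfg <- synth_config(n_genes = 300, frac_interaction = 0, seed = 100 + s)
    ab <- gen_abundance(cfg, "protein")
    h <- split_by_genotype(ab$table)
    dr <- differential_response(h$control, h$knockdown)
    sum(dr$padj_diff < 0.05, na.rm = TRUE)
  }, numeric(1))
  # with all-null features any rejection is a false discovery; BH keeps the
  # per-run family-wise rate of >= 1 rejection near the FDR level
  expect_lte(mean(hits > 0), 0.05 + 3 * sqrt(0.05 * 0.95 / 20))
})

test_that("layer overlap: Venn regions, flat table, Fisher oracle", {
  universe <- sprintf("g%02d", 1:40)
  sets <- list(A = universe[1:10], B = universe[6:20])
  ov <- layer_overlap(sets, universe)
  expect_equal(sum(ov$venn$count), 40L)
  expect_equal(ov$venn$count[ov$venn$region == "A&B"], 5L)
  expect_equal(ov$pairs$a, 5L)

  expect_error(layer_overlap(list(A = c("zzz")), universe), "outside the universe")

  # disjoint sets: zero intersection
  ov2 <- layer_overlap(list(A = universe[1:5], B = universe[6:10]), universe)
  expect_equal(ov2$venn$count[ov2$venn$region == "A&B"], 0L)

  # flat 2x2 table: odds ratio 1, p = 1
  u <- sprintf("x%02d", 1:40)
  ov3 <- layer_overlap(list(A = u[1:20], B = u[c(1:10, 21:30)]), u)
  expect_equal(ov3$pairs$odds_ratio, 1)
  expect_equal(ov3$pairs$p, 1)
})

test_that("Fisher p equals the hypergeometric tail enumeration", {
  # oracle: sum the probabilities of all tables (given margins) whose
  # point probability does not exceed that of the observed table
  fisher_oracle <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    support <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(support, r1, n - r1, c1)
    p_obs <- dhyper(a, r1, n - r1, c1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  # exhaustive over small margins
  for (r1 in c(2, 5, 9)) for (r2 in c(3, 6, 12)) {
    for (c1 in 0:min(12, r1 + r2)) {
      for (a in max(0, c1 - r2):min(r1, c1)) {
        b <- r1 - a; cc <- c1 - a; d <- r2 - cc
        expect_equal(fisher_exact_p(a, b, cc, d),
                     fisher_oracle(a, b, cc, d), tolerance = 1e-9)
      }
    }
  }
  # random tables with margins up to 50
  set.seed(77)
  for (i in 1:200) {
    r1 <- sample(1:50, 1); r2 <- sample(1:50, 1)
    c1 <- sample(0:(r1 + r2), 1)
    rng <- max(0, c1 - r2):min(r1, c1)
    a <- rng[sample.int(length(rng), 1)]
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    expect_equal(fisher_exact_p(a, b, cc, d), fisher_oracle(a, b, cc, d),
                 tolerance = 1e-9)
  }
})
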