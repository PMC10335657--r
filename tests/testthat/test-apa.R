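# NCOM, PAS calling, annotation extension, merging, size factors.

test_that("NCOM attains its boundary and uniform values", {
  L <- 1000L
  # all reads at the first base: 0.5/L, essentially fully proximal
  first <- compute_ncom(0L, 100, L)
  expect_equal(first$ncom, 0.5 / L, tolerance = 1e-15)
  # all reads at the last base: (L - 0.5)/L, essentially fully distal
  last <- compute_ncom(L - 1L, 100, L)
  expect_equal(last$ncom, (L - 0.5) / L, tolerance = 1e-15)
  # uniform profile: exactly 0.5
  unif <- compute_ncom(0:(L - 1L), rep(3, L), L)
  expect_equal(unif$ncom, 0.5, tolerance = 1e-15)
  # zero coverage: NA, not an exception
  z <- compute_ncom(integer(0), numeric(0), L)
  expect_true(is.na(z$ncom))
  expect_equal(z$total_reads, 0)
})

test_that("NCOM equals a naive two-pass oracle and is scale-invariant", {
  set.seed(31)
  for (i in 1:200) {
    L <- sample(200:3000, 1)
    k <- sample(1:50, 1)
    pos <- sample(0:(L - 1L), k)
    cnt <- runif(k, 0.1, 500)
    got <- compute_ncom(pos, cnt, L)
    # oracle: explicit accumulation loop
    tot <- 0; wsum <- 0
    for (j in seq_len(k)) {
      tot <- tot + cnt[j]
      wsum <- wsum + cnt[j] * (pos[j] + 0.5)
    }
    expect_equal(got$ncom, (wsum / tot) / L, tolerance = 1e-12)
    # uniform count rescaling leaves NCOM unchanged
    expect_equal(compute_ncom(pos, cnt * 17.3, L)$ncom, got$ncom,
                 tolerance = 1e-12)
  }
})

test_that("NCOM strictly increases when mass moves distally", {
  set.seed(8)
  L <- 500L
  pos <- 0:(L - 1L)
  cnt <- rpois(L, 2) + 1
  base <- compute_ncom(pos, cnt, L)$ncom
  for (i in 1:20) {
    idx <- which(cnt > 0)
    a <- idx[sample.int(length(idx), 1)]
    if (a == L) next
    rng <- (a + 1):L
    b <- rng[sample.int(length(rng), 1)]  # strictly more distal position
    cnt2 <- cnt
    cnt2[a] <- cnt2[a] - 1
    cnt2[b] <- cnt2[b] + 1
    expect_gt(compute_ncom(pos, cnt2, L)$ncom, base)
    cnt <- cnt2
    base <- compute_ncom(pos, cnt, L)$ncom
  }
})

test_that("ncom_table agrees with per-profile compute_ncom", {
  cfg <- synth_config(n_genes = 30, seed = 14)
  apa <- gen_apa_counts(cfg)
  nt <- ncom_table(apa$profiles, apa$utrs, apa$meta)
  prof <- as.data.frame(apa$profiles)
  for (i in sample(nrow(apa$utrs), 5)) {
    iso <- apa$utrs$isoform_id[i]
    L <- apa$utrs$length_L[i]
    for (s in sample(colnames(nt$values), 3)) {
      g <- prof[prof$isoform_id == iso & prof$sample_id == s, ]
      expect_equal(nt$values[iso, s], compute_ncom(g$offset, g$count, L)$ncom,
                   tolerance = 1e-12)
    }
  }
})

test_that("PAS calls: spikes, two sites, extension flag and bound", {
  cfg <- run_config()
  L <- 1000L
  # single spike at offset 120 -> one call covering window [100, 150)
  one <- call_pas(120L, 50, L, cfg)
  expect_equal(nrow(one), 1L)
  expect_equal(one$window_start, 100L)
  expect_equal(one$window_end, 150L)
  expect_false(one$is_extension)

  # spikes at 100 and 900 -> two calls
  two <- call_pas(c(100L, 900L), c(40, 60), L, cfg)
  expect_equal(nrow(two), 2L)

  # spike past the annotated end -> extension call
  ext <- call_pas(c(100L, L + 300L), c(40, 40), L, cfg)
  expect_true(any(ext$is_extension))
  expect_equal(ext$window_start[ext$is_extension], 1300L)

  # positions beyond the 5000 nt search bound are rejected
  expect_error(call_pas(L + 5001L, 40, L, cfg), "extension bound")

  # empty profile -> empty call set
  expect_equal(nrow(call_pas(integer(0), numeric(0), L, cfg)), 0L)

  # adjacent qualifying windows merge into one call
  merged <- call_pas(c(110L, 160L), c(30, 30), L, cfg)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$window_end - merged$window_start, 100L)
})

test_that("annotation extension uses the farthest call and is idempotent", {
  u <- utr_model("G1", "NM_1", "chr1", "+", 1000L, 2000L)  # L = 1000
  cfg <- run_config()
  no_ext <- call_pas(c(100L, 900L), c(40, 60), u$length_L, cfg)
  expect_identical(extend_annotation(u, no_ext), u)

  with_ext <- call_pas(c(100L, 1310L, 1330L), c(40, 20, 20), u$length_L, cfg)
  u2 <- extend_annotation(u, with_ext)
  expect_equal(u2$isoform_id, "NM_1_ext")
  expect_equal(u2$length_L, 1350L)  # farthest extension window ends at 1350

  # second pass finds no new extensions on the extended annotation
  again <- call_pas(c(100L, 1310L, 1330L), c(40, 20, 20), u2$length_L, cfg)
  expect_identical(extend_annotation(u2, again), u2)
})

test_that("identical-UTR isoforms merge; different ends do not; idempotent", {
  utrs <- rbind(
    utr_model("G1", "NM_1", "chr1", "+", 0L, 500L),
    utr_model("G1", "NM_2", "chr1", "+", 0L, 500L),
    utr_model("G1", "NM_3", "chr1", "+", 0L, 800L),
    utr_model("G2", "NM_4", "chr2", "-", 0L, 500L))
  m <- merge_identical_utrs(utrs, c(10, 5, 2, 7))
  expect_equal(nrow(m$utrs), 3L)
  expect_equal(m$utrs$isoform_id[1L], "NM_1|NM_2")
  expect_equal(unname(m$counts), c(15, 2, 7))
  m2 <- merge_identical_utrs(m$utrs, m$counts)
  expect_equal(m2$utrs$isoform_id, m$utrs$isoform_id)
  expect_equal(unname(m2$counts), unname(m$counts))
})

test_that("size factors: identity, doubling, duplicates, and oracles", {
  set.seed(4)
  # odd feature count: the raw-ratio median and the log-space median coincide
  # exactly, so one fixture serves both oracles
  m <- matrix(rpois(51 * 6, 80) + 1, 51, 6,
              dimnames = list(paste0("f", 1:51), paste0("s", 1:6)))

  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("d", 1:3)
  expect_equal(unname(size_factors(same)), rep(1, 3), tolerance = 1e-12)

  doubled <- cbind(m, dbl = 2 * m[, 1])
  sf <- size_factors(doubled)
  expect_equal(unname(sf["dbl"] / sf[1L]), 2, tolerance = 1e-12)

  # literal median-of-ratios reimplementation as oracle
  geo <- exp(rowMeans(log(m)))
  oracle <- apply(m, 2, function(col) median(col / geo))
  expect_equal(size_factors(m), oracle, tolerance = 1e-12)

  # independent package oracle
  skip_if_not_installed("DESeq2")
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("distal usage ratios behave at the boundaries and flag overshoot", {
  expect_equal(distal_usage(5, 5)$ratio, 1)
  expect_equal(distal_usage(0, 5)$ratio, 0)
  over <- distal_usage(6, 5)
  expect_true(over$flag_gt1)
  expect_equal(over$ratio, 1.2)
  expect_error(distal_usage(1, 0), "positive")
})

test_that("replicate-averaged distal-usage ratios separate genotypes by t test", {
  # three experiments x three technical replicates per genotype; knockdown
  # halves distal usage. Replicates are averaged per experiment before the
  # two-sample t test, so n is the experiment count.
  set.seed(99)
  exp_means <- function(p) replicate(3, mean(distal_usage(
    rnorm(3, p * 100, 5), rep(100, 3))$ratio))
  ctl <- exp_means(0.6)
  kd <- exp_means(0.3)
  tt <- t.test(ctl, kd)
  expect_lt(tt$p.value, 0.01)
  expect_equal(length(ctl), 3L)
})
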