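# Synthetic-data generators. Every pipeline input kind is generated from an
# explicit statistical model with ground truth recorded, so downstream
# estimators can be checked for parameter recovery without any external data.
#
# The defaults emulate the study design the analyses assume: two genotypes
# (control / knockdown), three culture temperatures (32/37/39 degC) for the
# omics layers with 3 transcript-level and 4 protein-level replicates, four
# recording temperatures (32/35/37/39 degC) with 4 wells each for
# bioluminescence (16 wells per genotype), two-PAS 3' UTR isoform mixtures
# with a logistic model on proximal usage, log-linear temperature trends on
# abundances, and exponential decay chases over 0-8 h.

#' Parameters of the synthetic-data generative model
#'
#' All generators are pure functions of `(cfg, seed)`.
#'
#' Proximal-PAS usage follows
#' `pi(g, T) = logistic(b0 + bg*1[KD] + bT*(T - 37) + bgT*1[KD]*(T - 37))`,
#' with the genotype x temperature interaction `bgT` active only in the first
#' `ceiling(frac_interaction * n_genes)` genes. 3'-end read positions are a
#' mixture `pi * N(q*L, sd) + (1 - pi) * N(d*L, sd)` truncated to `[0, L)`,
#' so the expected NCOM is approximately `pi*q + (1 - pi)*d`.
#'
#' Abundances follow `log2 y = alpha_i + dg_i*1[KD] + bT_i*(T - 37) +
#' c_i*1[KD]*(T - 37) + N(0, sigma)`, with `c_i != 0` only in the interaction
#' subset; transcript values are exponentiated and rounded to counts,
#' proteins stay on the log2-intensity scale.
#'
#' Bioluminescence wells follow
#' `y(t) = M(t) * [1 + A exp(-lambda t) cos(2 pi (t - phi) / tau(g, T))] + eps`
#' with baseline `M(t) = m0 exp(-t / 96 h)` and
#' `tau(g, T) = tau0_g + b_g * (T - 35)`.
#'
#' @param n_genes number of features.
#' @param frac_interaction fraction of features with a genotype x temperature
#'   interaction; the interaction subset is always the first
#'   `ceiling(frac_interaction * n_genes)` feature ids.
#' @param pas_proximal_rel,pas_distal_rel relative PAS positions q < d in (0,1).
#' @param usage_intercept logit of proximal usage in control at 37 degC.
#' @param usage_genotype_effect additive logit shift in knockdown; positive
#'   values shift usage proximally (3' UTR shortening).
#' @param usage_temp_slope logit change per degC (shared baseline).
#' @param usage_interaction extra logit per degC in knockdown, interaction
#'   subset only.
#' @param abundance_base_log2 mean baseline log2 abundance (transcripts).
#' @param abundance_base_sd_log2 between-feature SD of the baseline.
#' @param abundance_genotype_sd_log2 SD of random genotype main effects.
#' @param abundance_temp_slope_log2 mean temperature slope, log2 per degC.
#' @param abundance_temp_slope_sd_log2 between-feature SD of the slope.
#' @param abundance_interaction_log2 |interaction| slope, log2 per degC
#'   (random sign per feature), interaction subset only.
#' @param abundance_noise_log2 replicate noise SD, log2 units.
#' @param protein_base_log2 mean baseline log2 LFQ intensity.
#' @param nb_dispersion negative-binomial dispersion of per-sample read
#'   totals (Poisson as dispersion -> 0).
#' @param reads_per_gene_meanlog,reads_per_gene_sdlog lognormal parameters of
#'   the per-gene mean 3'-end read depth.
#' @param utr_length_meanlog,utr_length_sdlog lognormal parameters of 3' UTR
#'   lengths (nucleotides).
#' @param positional_sd_nt SD of read positions around each PAS, nucleotides.
#' @param period_base_h named vector: free-running period at 35 degC per
#'   genotype, hours.
#' @param period_slope_h_per_C named vector: period change per degC per
#'   genotype.
#' @param rel_amplitude relative oscillation amplitude A.
#' @param damping_per_h amplitude damping rate lambda, 1/h.
#' @param phase_h phase phi, hours.
#' @param baseline_m0 baseline magnitude m0, signal units.
#' @param baseline_decay_h baseline decay time t_m, hours.
#' @param noise_sd additive recording noise, signal units.
#' @param sampling_interval_h plate sampling interval, hours.
#' @param record_days recording length, days.
#' @param wells_per_condition wells per genotype x temperature.
#' @param temperatures_biolum recording temperatures, degC.
#' @param temperatures culture temperatures for the omics layers, degC.
#' @param reps_transcript,reps_ncom,reps_protein replicates per condition.
#' @param seed integer seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000,
                         frac_interaction = 0.1,
                         pas_proximal_rel = 0.2,
                         pas_distal_rel = 0.8,
                         usage_intercept = -1,
                         usage_genotype_effect = 2,
                         usage_temp_slope = -0.01,
                         usage_interaction = 0.15,
                         abundance_base_log2 = 8,
                         abundance_base_sd_log2 = 1.5,
                         abundance_genotype_sd_log2 = 0.3,
                         abundance_temp_slope_log2 = 0.02,
                         abundance_temp_slope_sd_log2 = 0.05,
                         abundance_interaction_log2 = 0.15,
                         abundance_noise_log2 = 0.15,
                         protein_base_log2 = 25,
                         nb_dispersion = 0.05,
                         reads_per_gene_meanlog = log(300),
                         reads_per_gene_sdlog = 0.4,
                         utr_length_meanlog = log(1500),
                         utr_length_sdlog = 0.4,
                         positional_sd_nt = 30,
                         period_base_h = c(control = 24.014, knockdown = 26.029),
                         period_slope_h_per_C = c(control = -0.1286, knockdown = -0.4571),
                         rel_amplitude = 0.4,
                         damping_per_h = 0.01,
                         phase_h = 2,
                         baseline_m0 = 10000,
                         baseline_decay_h = 96,
                         noise_sd = 100,
                         sampling_interval_h = 0.5,
                         record_days = 5.5,
                         wells_per_condition = 4,
                         temperatures_biolum = c(32, 35, 37, 39),
                         temperatures = c(32, 37, 39),
                         reps_transcript = 3,
                         reps_ncom = 3,
                         reps_protein = 4,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (!(cfg$pas_proximal_rel > 0 && cfg$pas_proximal_rel < cfg$pas_distal_rel &&
        cfg$pas_distal_rel < 1))
    stop("synth_config: require 0 < pas_proximal_rel < pas_distal_rel < 1")
  if (cfg$frac_interaction < 0 || cfg$frac_interaction > 1)
    stop("synth_config: frac_interaction must be in [0, 1]")
  for (f in c("reps_transcript", "reps_ncom", "reps_protein"))
    if (cfg[[f]] < 2) stop("synth_config: ", f, " must be >= 2")
  if (cfg$n_genes < 1) stop("synth_config: n_genes must be >= 1")
  if (!all(GENOTYPES %in% names(cfg$period_base_h)) ||
      !all(GENOTYPES %in% names(cfg$period_slope_h_per_C)))
    stop("synth_config: period parameters must be named by genotype (",
         paste(GENOTYPES, collapse = ", "), ")")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synth_config")
}

# interaction subset: the FIRST ceiling(frac * n) feature ids
interaction_index <- function(cfg) {
  k <- ceiling(cfg$frac_interaction * cfg$n_genes)
  if (k == 0) integer(0) else seq_len(k)
}

gene_ids <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))

logistic <- function(x) 1 / (1 + exp(-x))

# NB draw that degenerates to Poisson as dispersion -> 0
rnbinom_disp <- function(n, mu, dispersion) {
  if (dispersion <= 1e-12) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

## ---- bioluminescence -------------------------------------------------------

#' Generate a synthetic bioluminescence plate
#'
#' One well per genotype x recording temperature x replicate on a regular
#' sampling grid. The true period of each well,
#' `tau(g, T) = tau0_g + b_g * (T - 35)`, is recorded in the truth table.
#'
#' @param cfg `synth_config`.
#' @return list with `plate` (data.frame, `time_h` + one column per well),
#'   `meta` (sample annotations) and `truth` (per-well true parameters).
#' @export
gen_bioluminescence <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  t <- seq(0, cfg$record_days * 24, by = cfg$sampling_interval_h)
  design <- expand.grid(replicate = seq_len(cfg$wells_per_condition),
                        temperature_C = cfg$temperatures_biolum,
                        genotype = GENOTYPES,
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("well_%s_T%g_r%d",
                              substr(design$genotype, 1, 2),
                              design$temperature_C, design$replicate)
  tau <- cfg$period_base_h[design$genotype] +
    cfg$period_slope_h_per_C[design$genotype] * (design$temperature_C - 35)
  M <- cfg$baseline_m0 * exp(-t / cfg$baseline_decay_h)
  plate <- data.frame(time_h = t, check.names = FALSE)
  for (i in seq_len(nrow(design))) {
    osc <- 1 + cfg$rel_amplitude * exp(-cfg$damping_per_h * t) *
      cos(2 * pi * (t - cfg$phase_h) / tau[i])
    plate[[design$sample_id[i]]] <- M * osc + rnorm(length(t), 0, cfg$noise_sd)
  }
  meta <- data.frame(sample_id = design$sample_id,
                     genotype = design$genotype,
                     temperature_C = design$temperature_C,
                     replicate = design$replicate,
                     layer = "bioluminescence",
                     stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = design$sample_id,
                      genotype = design$genotype,
                      temperature_C = design$temperature_C,
                      period_h = unname(tau),
                      rel_amplitude = cfg$rel_amplitude,
                      damping_per_h = cfg$damping_per_h,
                      phase_h = cfg$phase_h,
                      stringsAsFactors = FALSE)
  list(plate = plate, meta = meta, truth = truth)
}

## ---- 3'-end read profiles (APA) --------------------------------------------

#' Generate synthetic 3'-end read profiles for a two-PAS isoform mixture
#'
#' Per gene of UTR length L, each sample's reads fall at the proximal PAS
#' (relative position q) with probability `pi(g, T)` and at the distal PAS
#' (position d) otherwise, with Gaussian positional scatter truncated to
#' `[0, L)`. Per-sample totals are negative-binomially dispersed around the
#' gene's mean depth. The truth table stores `pi` and the expected NCOM
#' `pi*q + (1 - pi)*d` per gene and sample.
#'
#' @param cfg `synth_config`.
#' @return list with `utrs` (UTR models), `profiles` (data.table:
#'   `isoform_id`, `sample_id`, `offset`, `count`), `meta`, and `truth`
#'   (data.table: gene, sample, pi_proximal, ncom_expected).
#' @export
gen_apa_counts <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  genes <- gene_ids(cfg)
  L <- pmax(200L, as.integer(round(exp(rnorm(cfg$n_genes, cfg$utr_length_meanlog,
                                             cfg$utr_length_sdlog)))))
  depth <- exp(rnorm(cfg$n_genes, cfg$reads_per_gene_meanlog,
                     cfg$reads_per_gene_sdlog))
  utrs <- data.frame(gene = genes,
                     isoform_id = paste0(genes, ".1"),
                     chrom = "chrS",
                     strand = rep(c("+", "-"), length.out = cfg$n_genes),
                     utr_start = 0L, utr_end = L, length_L = L,
                     stringsAsFactors = FALSE)

  design <- expand.grid(replicate = seq_len(cfg$reps_ncom),
                        temperature_C = cfg$temperatures,
                        genotype = GENOTYPES,
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("ncom_%s_T%g_r%d",
                              substr(design$genotype, 1, 2),
                              design$temperature_C, design$replicate)
  meta <- data.frame(design[c("sample_id", "genotype", "temperature_C",
                              "replicate")],
                     layer = "ncom", stringsAsFactors = FALSE)

  ia <- interaction_index(cfg)
  is_kd <- as.numeric(design$genotype == "knockdown")
  tc <- design$temperature_C - 37

  # gene x sample grids (vectorized over the full cross)
  ns <- nrow(design)
  gidx <- rep(seq_len(cfg$n_genes), each = ns)
  sidx <- rep(seq_len(ns), times = cfg$n_genes)
  bgT <- ifelse(gidx %in% ia, cfg$usage_interaction, 0)
  eta <- cfg$usage_intercept +
    cfg$usage_genotype_effect * is_kd[sidx] +
    cfg$usage_temp_slope * tc[sidx] +
    bgT * is_kd[sidx] * tc[sidx]
  pi_prox <- logistic(eta)
  totals <- rnbinom_disp(length(gidx), depth[gidx], cfg$nb_dispersion)

  truth <- data.table::data.table(
    gene = genes[gidx],
    isoform_id = utrs$isoform_id[gidx],
    sample_id = design$sample_id[sidx],
    genotype = design$genotype[sidx],
    temperature_C = design$temperature_C[sidx],
    pi_proximal = pi_prox,
    ncom_expected = pi_prox * cfg$pas_proximal_rel +
      (1 - pi_prox) * cfg$pas_distal_rel,
    total_reads = totals
  )

  # draw every read at once
  n_prox <- rbinom(length(totals), totals, pi_prox)
  n_dist <- totals - n_prox
  li <- L[gidx]
  mk_positions <- function(nvec, center_rel) {
    idx <- rep.int(seq_along(nvec), nvec)
    mu <- center_rel * li[idx]
    pos <- round(rnorm(length(idx), mu, cfg$positional_sd_nt))
    pos <- pmin(pmax(pos, 0), li[idx] - 1L)
    data.table::data.table(cell = idx, offset = as.integer(pos))
  }
  reads <- data.table::rbindlist(list(
    mk_positions(n_prox, cfg$pas_proximal_rel),
    mk_positions(n_dist, cfg$pas_distal_rel)
  ))
  cell <- offset <- count <- NULL  # appease R CMD check NSE
  profiles <- reads[, .(count = .N), by = .(cell, offset)]
  profiles[, `:=`(isoform_id = utrs$isoform_id[gidx[cell]],
                  sample_id = design$sample_id[sidx[cell]])]
  profiles[, cell := NULL]
  data.table::setcolorder(profiles, c("isoform_id", "sample_id", "offset", "count"))
  data.table::setkey(profiles, isoform_id, sample_id, offset)

  list(utrs = utrs, profiles = profiles[], meta = meta, truth = truth)
}

## ---- abundance layers ------------------------------------------------------

#' Generate a synthetic abundance layer (transcript counts or protein log2)
#'
#' `log2 y = alpha_i + dg_i*1[KD] + bT_i*(T - 37) + c_i*1[KD]*(T - 37) +
#' N(0, sigma)`. The interaction `c_i` is nonzero only for the first
#' `ceiling(frac_interaction * n_genes)` features, with random sign.
#' Transcript values are exponentiated and rounded to counts; proteins stay
#' on the log2 scale.
#'
#' @param cfg `synth_config`.
#' @param layer "transcript" or "protein".
#' @return list with `table` (a [feature_table()]) and `truth` (per-feature
#'   data.frame: alpha, genotype effect, temperature slope, interaction, and
#'   `is_interaction`).
#' @export
gen_abundance <- function(cfg, layer = c("transcript", "protein")) {
  stopifnot(inherits(cfg, "synth_config"))
  layer <- match.arg(layer)
  set.seed(cfg$seed + if (layer == "transcript") 2L else 3L)
  reps <- if (layer == "transcript") cfg$reps_transcript else cfg$reps_protein
  base <- if (layer == "transcript") cfg$abundance_base_log2 else cfg$protein_base_log2
  genes <- gene_ids(cfg)
  ia <- interaction_index(cfg)

  alpha <- rnorm(cfg$n_genes, base, cfg$abundance_base_sd_log2)
  dg <- rnorm(cfg$n_genes, 0, cfg$abundance_genotype_sd_log2)
  bT <- rnorm(cfg$n_genes, cfg$abundance_temp_slope_log2,
              cfg$abundance_temp_slope_sd_log2)
  ci <- numeric(cfg$n_genes)
  if (length(ia))
    ci[ia] <- sample(c(-1, 1), length(ia), replace = TRUE) *
      cfg$abundance_interaction_log2

  design <- expand.grid(replicate = seq_len(reps),
                        temperature_C = cfg$temperatures,
                        genotype = GENOTYPES,
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_T%g_r%d", substr(layer, 1, 2),
                              substr(design$genotype, 1, 2),
                              design$temperature_C, design$replicate)
  is_kd <- as.numeric(design$genotype == "knockdown")
  tc <- design$temperature_C - 37

  mu <- outer(alpha, rep(1, nrow(design))) +
    outer(dg, is_kd) + outer(bT, tc) + outer(ci, is_kd * tc)
  vals <- mu + matrix(rnorm(length(mu), 0, cfg$abundance_noise_log2),
                      nrow = nrow(mu))
  if (layer == "transcript") vals <- round(2^vals)
  dimnames(vals) <- list(genes, design$sample_id)

  meta <- data.frame(design[c("sample_id", "genotype", "temperature_C",
                              "replicate")],
                     layer = layer, stringsAsFactors = FALSE)
  truth <- data.frame(feature = genes, alpha = alpha, genotype_effect = dg,
                      temp_slope_log2 = bT, interaction_log2 = ci,
                      is_interaction = seq_len(cfg$n_genes) %in% ia,
                      stringsAsFactors = FALSE)
  list(table = feature_table(vals, meta, layer), truth = truth)
}

## ---- decay chases ----------------------------------------------------------

#' Generate a synthetic transcription-shutoff decay series
#'
#' `y(t) = y0 * 2^(-t / half_life) * exp(eps)`, `eps ~ N(0, noise_sd)` on the
#' natural-log scale, sampled over a 0-8 h chase.
#'
#' @param half_life_h true half-life, hours.
#' @param n_timepoints number of time points over the chase (default 7).
#' @param noise_sd multiplicative noise SD in natural-log units.
#' @param seed integer seed.
#' @param y0 initial abundance.
#' @param t_max_h chase length, hours (default 8).
#' @return data.frame with `time_h`, `value`, and the true `half_life_h`.
#' @export
gen_decay_series <- function(half_life_h, n_timepoints = 7, noise_sd = 0,
                             seed = 1L, y0 = 100, t_max_h = 8) {
  if (half_life_h <= 0) stop("gen_decay_series: half_life_h must be positive")
  set.seed(as.integer(seed))
  t <- seq(0, t_max_h, length.out = n_timepoints)
  y <- y0 * 2^(-t / half_life_h) * exp(rnorm(n_timepoints, 0, noise_sd))
  data.frame(time_h = t, value = y, half_life_h = half_life_h)
}
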