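# shared fixtures, built in code

quiet_logs <- function() options(circatemp.log_level = "quiet")
quiet_logs()

# minimal valid metadata for n samples of one layer
mk_meta <- function(ids, genotype = "control", temperature = 37,
                    replicate = NULL, layer = "transcript") {
  n <- length(ids)
  data.frame(sample_id = ids,
             genotype = rep_len(genotype, n),
             temperature_C = rep_len(temperature, n),
             replicate = if (is.null(replicate)) seq_len(n) else rep_len(replicate, n),
             layer = rep_len(layer, n),
             stringsAsFactors = FALSE)
}

# plate traces from a generated bioluminescence set
traces_from_gen <- function(bl) {
  wells <- setdiff(names(bl$plate), "time_h")
  out <- lapply(wells, function(w)
    biolum_trace(bl$plate$time_h, bl$plate[[w]],
                 bl$meta[match(w, bl$meta$sample_id), , drop = FALSE]))
  names(out) <- wells
  out
}

# two-group (temperature, observable) samples with given slopes for the
# differential-slope test
mk_slope_group <- function(slope, intercept_at_35, temps, reps, sd, seed) {
  set.seed(seed)
  tt <- rep(temps, each = reps)
  cbind(tt, intercept_at_35 + slope * (tt - 35) + rnorm(length(tt), 0, sd))
}
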