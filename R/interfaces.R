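# File formats, run configuration and containers shared by all stages.
#
# Formats: plate CSV (column "time_h" + one column per well), metadata TSV
# (sample_id, genotype, temperature_C, replicate, layer), feature TSV (first
# column feature id), BED6 for UTR/PAS annotations (0-based half-open),
# YAML run config, JSON run manifest. Missing values are encoded "NA" and are
# never silently imputed.

GENOTYPES <- c("control", "knockdown")
LAYERS <- c("bioluminescence", "ncom", "transcript", "protein", "decay")

#' Run configuration
#'
#' Tunable parameters shared across pipeline stages, with field-level
#' validation. Values mirror a flat YAML config file (see
#' [read_run_config()]); command-line flags override file values.
#'
#' @param detrend_window_h moving-average window for detrending, hours.
#' @param fit_error_max QC threshold on the damped-cosine fit error; wells
#'   with larger error are discarded.
#' @param fit_skip_h initial transient excluded from rhythm fitting, hours.
#' @param fit_trim_end_h trailing stretch excluded from rhythm fitting, hours;
#'   within half a detrend window of the recording end the shrinking-window
#'   moving average suppresses the oscillation, so the default equals half
#'   the detrend window.
#' @param pas_window_nt scanning-window length for PAS discovery, nucleotides.
#' @param pas_max_extension_nt maximal search distance beyond the annotated
#'   3' UTR end, nucleotides.
#' @param pas_min_abs_count minimal summed read count for a window to be
#'   called a PAS.
#' @param pas_min_frac minimal fraction of the profile total for a PAS call.
#' @param fdr_level Benjamini-Hochberg FDR level for all screens.
#' @param q10_reference_span reference span of the Q10 coefficient, degrees.
#' @param temp_low,temp_high evaluation temperatures for Q10, degrees C.
#' @param tau_grid multi-start grid of trial periods for the damped-cosine
#'   fit, hours.
#' @param seed integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(detrend_window_h = 24,
                       fit_error_max = 0.3,
                       fit_skip_h = 24,
                       fit_trim_end_h = 12,
                       pas_window_nt = 50,
                       pas_max_extension_nt = 5000,
                       pas_min_abs_count = 10,
                       pas_min_frac = 0.01,
                       fdr_level = 0.05,
                       q10_reference_span = 10,
                       temp_low = 32,
                       temp_high = 39,
                       tau_grid = seq(18, 36, by = 1),
                       seed = 1L) {
  cfg <- list(detrend_window_h = detrend_window_h,
              fit_error_max = fit_error_max,
              fit_skip_h = fit_skip_h,
              fit_trim_end_h = fit_trim_end_h,
              pas_window_nt = as.integer(pas_window_nt),
              pas_max_extension_nt = as.integer(pas_max_extension_nt),
              pas_min_abs_count = pas_min_abs_count,
              pas_min_frac = pas_min_frac,
              fdr_level = fdr_level,
              q10_reference_span = q10_reference_span,
              temp_low = temp_low, temp_high = temp_high,
              tau_grid = tau_grid,
              seed = as.integer(seed))
  for (f in c("detrend_window_h", "fit_error_max", "pas_window_nt",
              "pas_max_extension_nt", "fdr_level", "q10_reference_span")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !(cfg[[f]] > 0))
      stop("run_config: field '", f, "' must be a single positive number")
  }
  if (cfg$fdr_level >= 1) stop("run_config: fdr_level must be in (0, 1)")
  if (cfg$fit_skip_h < 0) stop("run_config: fit_skip_h must be nonnegative")
  if (cfg$fit_trim_end_h < 0) stop("run_config: fit_trim_end_h must be nonnegative")
  structure(cfg, class = "run_config")
}

#' Read a flat YAML run config
#'
#' Unknown keys are rejected; present keys override [run_config()] defaults.
#' @param path YAML file.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("read_run_config: unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Write a run config as flat YAML
#' @param cfg `run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## ---- sample metadata -------------------------------------------------------

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `genotype` (control/knockdown),
#' `temperature_C`, `replicate`, `layer`. Sample ids must be unique,
#' temperatures finite within \[20, 45\], replicates positive integers.
#'
#' @param path TSV file.
#' @return data.frame of validated annotations.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  validate_metadata(meta)
}

validate_metadata <- function(meta) {
  need <- c("sample_id", "genotype", "temperature_C", "replicate", "layer")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("metadata: duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  bad <- !meta$genotype %in% GENOTYPES
  if (any(bad))
    stop("metadata: genotype must be one of ", paste(GENOTYPES, collapse = "/"),
         "; offending row(s): ", paste(which(bad), collapse = ", "))
  t_ok <- is.finite(meta$temperature_C) & meta$temperature_C >= 20 & meta$temperature_C <= 45
  if (!all(t_ok))
    stop("metadata: temperature_C must be finite in [20, 45]; offending row(s): ",
         paste(which(!t_ok), collapse = ", "))
  r_ok <- is.finite(meta$replicate) & meta$replicate >= 1 & meta$replicate == round(meta$replicate)
  if (!all(r_ok))
    stop("metadata: replicate must be a positive integer; offending row(s): ",
         paste(which(!r_ok), collapse = ", "))
  bad_layer <- !meta$layer %in% LAYERS
  if (any(bad_layer))
    stop("metadata: layer must be one of ", paste(LAYERS, collapse = "/"),
         "; offending row(s): ", paste(which(bad_layer), collapse = ", "))
  meta
}

#' Write sample metadata
#' @param meta data.frame as returned by [read_metadata()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- bioluminescence plates ------------------------------------------------

#' Read a plate-format bioluminescence file
#'
#' The plate file is CSV with a `time_h` column (hours, strictly increasing)
#' and one column per well. Wells are joined to the metadata by `sample_id`;
#' wells absent from the metadata are rejected.
#'
#' @param path plate CSV.
#' @param meta_path metadata TSV (see [read_metadata()]).
#' @return named list of `biolum_trace` objects (fields `time`, `signal`,
#'   `annotation`), one per well, each sorted by time.
#' @export
read_plate_timeseries <- function(path, meta_path) {
  plate <- utils::read.table(path, header = TRUE, sep = ",",
                             stringsAsFactors = FALSE, check.names = FALSE)
  meta <- read_metadata(meta_path)
  if (!"time_h" %in% names(plate))
    stop("plate file ", path, ": missing 'time_h' column")
  tm <- plate$time_h
  if (!is.numeric(tm) || anyNA(tm))
    stop("plate file ", path, ": unparsable numeric in column 'time_h'")
  if (any(diff(tm) <= 0))
    stop("plate file ", path, ": non-monotonic time column at row ",
         which(diff(tm) <= 0)[1L] + 1L)
  if (any(tm < 0))
    stop("plate file ", path, ": negative time at row ", which(tm < 0)[1L])
  wells <- setdiff(names(plate), "time_h")
  if (anyDuplicated(wells))
    stop("plate file ", path, ": duplicate well id: ",
         paste(unique(wells[duplicated(wells)]), collapse = ", "))
  missing_meta <- setdiff(wells, meta$sample_id)
  if (length(missing_meta))
    stop("plate file ", path, ": well(s) missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  traces <- lapply(wells, function(w) {
    y <- plate[[w]]
    if (!is.numeric(y))
      stop("plate file ", path, ": unparsable numeric in column '", w, "'")
    biolum_trace(tm, y, meta[match(w, meta$sample_id), , drop = FALSE])
  })
  names(traces) <- wells
  traces
}

#' Construct a bioluminescence trace
#' @param time numeric, hours, strictly increasing, nonnegative.
#' @param signal numeric, same length.
#' @param annotation one-row data.frame of sample annotations (or NULL).
#' @return object of class `biolum_trace`.
#' @export
biolum_trace <- function(time, signal, annotation = NULL) {
  if (length(time) != length(signal))
    stop("biolum_trace: time and signal lengths differ")
  if (any(time < 0)) stop("biolum_trace: negative time")
  if (is.unsorted(time, strictly = TRUE))
    stop("biolum_trace: time must be strictly increasing")
  structure(list(time = as.numeric(time), signal = as.numeric(signal),
                 annotation = annotation),
            class = "biolum_trace")
}

#' Write traces back to a plate CSV
#'
#' All traces must share one time grid.
#' @param traces list of `biolum_trace`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_plate_timeseries <- function(traces, path) {
  tm <- traces[[1L]]$time
  for (tr in traces)
    if (!isTRUE(all.equal(tr$time, tm)))
      stop("write_plate_timeseries: traces are not on a common time grid")
  plate <- data.frame(time_h = tm, check.names = FALSE)
  for (w in names(traces)) plate[[w]] <- traces[[w]]$signal
  utils::write.table(plate, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- feature tables --------------------------------------------------------

#' Construct a feature table (one omics layer)
#'
#' A features x samples matrix with per-sample annotations. NCOM values must
#' lie in \[0, 1\] (or NA); transcript counts must be nonnegative.
#'
#' @param values numeric matrix, rownames = feature ids, colnames = sample ids.
#' @param meta data.frame of sample annotations covering every column.
#' @param layer one of "ncom", "transcript", "protein".
#' @return object of class `feature_table` with elements `values`, `meta`,
#'   `layer` (meta rows aligned to columns).
#' @export
feature_table <- function(values, meta, layer) {
  layer <- match.arg(layer, c("ncom", "transcript", "protein"))
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature_table: values must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("feature_table: duplicate feature id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  meta <- validate_metadata(meta)
  absent <- setdiff(colnames(values), meta$sample_id)
  if (length(absent))
    stop("feature_table: sample(s) absent from metadata: ",
         paste(absent, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  if (layer == "ncom") {
    v <- values[is.finite(values)]
    if (length(v) && (any(v < 0) || any(v > 1)))
      stop("feature_table: ncom values must be in [0, 1] or NA")
  }
  if (layer == "transcript") {
    v <- values[is.finite(values)]
    if (length(v) && any(v < 0))
      stop("feature_table: negative counts in transcript layer")
  }
  structure(list(values = values, meta = meta, layer = layer),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s]: %d features x %d samples\n",
              x$layer, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a feature table from TSV
#'
#' First column is the feature id; remaining columns are samples that must
#' all be present in the metadata.
#'
#' @param path feature TSV.
#' @param meta_path metadata TSV.
#' @param layer one of "ncom", "transcript", "protein".
#' @return `feature_table`.
#' @export
read_feature_table <- function(path, meta_path, layer) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("feature table ", path, ": no sample columns")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("feature table ", path, ": duplicate feature id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("feature table ", path, ": non-numeric sample column(s)")
  rownames(m) <- ids
  feature_table(m, read_metadata(meta_path), layer)
}

#' Write a feature table to TSV
#' @param table `feature_table`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(feature = rownames(table$values), table$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- UTR annotations (BED6) ------------------------------------------------

#' Construct a 3' UTR model
#' @param gene gene symbol.
#' @param isoform_id isoform id; suffix "_ext" marks extended isoforms.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param utr_start 0-based start.
#' @param utr_end exclusive end; must exceed `utr_start`.
#' @return one-row data.frame with a derived `length_L` column.
#' @export
utr_model <- function(gene, isoform_id, chrom, strand, utr_start, utr_end) {
  if (!strand %in% c("+", "-"))
    stop("utr_model: strand must be '+' or '-', got '", strand, "'")
  if (!(utr_end > utr_start))
    stop("utr_model: utr_end must exceed utr_start (", isoform_id, ")")
  data.frame(gene = gene, isoform_id = isoform_id, chrom = chrom,
             strand = strand, utr_start = as.integer(utr_start),
             utr_end = as.integer(utr_end),
             length_L = as.integer(utr_end - utr_start),
             stringsAsFactors = FALSE)
}

#' Read 3' UTR annotations from BED6
#'
#' BED6 dialect, 0-based half-open: chrom, start, end, name, score, strand.
#' The name field is `gene|isoform`; an isoform id ending in "_ext" marks an
#' extended annotation.
#'
#' @param path BED file.
#' @return data.frame of UTR models (one row per record).
#' @export
read_utr_annotation <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1L)
  iso <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else p[1L], "")
  out <- lapply(seq_len(nrow(bed)), function(i)
    utr_model(gene[i], iso[i], bed$chrom[i], bed$strand[i],
              bed$start[i], bed$end[i]))
  do.call(rbind, out)
}

#' Write UTR annotations as BED6
#' @param utrs data.frame of UTR models.
#' @param path output BED.
#' @param score numeric vector recycled into the score column (default 0).
#' @return `path`, invisibly.
#' @export
write_utr_annotation <- function(utrs, path, score = 0) {
  bed <- data.frame(chrom = utrs$chrom, start = utrs$utr_start,
                    end = utrs$utr_end,
                    name = paste(utrs$gene, utrs$isoform_id, sep = "|"),
                    score = score, strand = utrs$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- run manifest and logging ----------------------------------------------

#' Write a JSON run manifest
#'
#' Records the subcommand, config, seed, input files with md5 hashes, and
#' output files, so chained stages can be audited.
#' @param path output JSON.
#' @param stage subcommand name.
#' @param cfg `run_config`.
#' @param inputs,outputs character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, cfg, inputs, outputs) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(list(stage = stage,
                            config = unclass(cfg),
                            seed = cfg$seed,
                            inputs = hashes,
                            outputs = as.list(outputs)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# stage logging: n inputs, n passing QC, n outputs
ct_log <- function(stage, ...) {
  lvl <- getOption("circatemp.log_level", "info")
  if (identical(lvl, "quiet")) return(invisible())
  message(sprintf("[circatemp:%s] %s", stage, sprintf(...)))
}
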