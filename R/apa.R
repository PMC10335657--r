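# Alternative-polyadenylation quantification: the normalized center of mass
# (NCOM) of 3'-end reads along a 3' UTR, scanning-window PAS discovery with
# annotation extension, identical-UTR merging, median-of-ratios size factors
# and distal-usage ratios.
#
# Position convention: offsets are transcript-oriented for BOTH strands --
# 0 at the 5' end of the UTR (next to the stop codon), increasing 3'-ward.
# Genomic minus-strand profiles must be reversed on ingest, so that NCOM
# always means "relative distance toward the distal end".

#' Normalized center of mass of a 3'-end read profile
#'
#' The center of mass is the count-weighted mean read position,
#' `com = sum(c_i * (p_i + 0.5)) / sum(c_i)`, and `ncom = com / L`. The
#' half-base offset makes a uniform profile map to exactly 0.5 and keeps
#' single-base profiles at the first/last base strictly inside (0, 1):
#' NCOM near 0 means fully proximal PAS usage (short 3' UTR), near 1 fully
#' distal usage.
#'
#' @param positions integer vector of read offsets in `[0, L)`.
#' @param counts nonnegative read counts per position.
#' @param length_L 3' UTR length in nucleotides.
#' @return list with `ncom`, `com`, `total_reads`; `ncom`/`com` are NA when
#'   the profile has zero total count.
#' @examples
#' compute_ncom(0:9, rep(1, 10), 10)$ncom  # uniform profile -> 0.5
#' @export
compute_ncom <- function(positions, counts, length_L) {
  if (length(positions) != length(counts))
    stop("compute_ncom: positions and counts lengths differ")
  if (any(counts < 0)) stop("compute_ncom: negative counts")
  if (length(positions) && any(positions < 0 | positions >= length_L))
    stop("compute_ncom: positions must lie in [0, length_L)")
  total <- sum(counts)
  if (total == 0)
    return(list(ncom = NA_real_, com = NA_real_, total_reads = 0))
  com <- sum(counts * (positions + 0.5)) / total
  list(ncom = com / length_L, com = com, total_reads = total)
}

#' NCOM matrix from per-sample read profiles
#'
#' Applies the [compute_ncom()] weighted mean per isoform x sample and
#' assembles the `feature_table` the downstream screens consume.
#' Zero-coverage isoform/sample cells yield NA and a logged count.
#'
#' @param profiles data.frame/data.table with columns `isoform_id`,
#'   `sample_id`, `offset`, `count`.
#' @param utrs UTR models (data.frame with `isoform_id`, `length_L`).
#' @param meta sample metadata covering every sample in `profiles`.
#' @return `feature_table` (layer "ncom") of NCOM values; isoforms or samples
#'   with no reads are NA.
#' @export
ncom_table <- function(profiles, utrs, meta) {
  dt <- data.table::as.data.table(profiles)
  need <- c("isoform_id", "sample_id", "offset", "count")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("ncom_table: profiles missing column(s): ", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(dt$isoform_id), utrs$isoform_id)
  if (length(unknown))
    stop("ncom_table: profile isoform(s) not in annotation: ",
         paste(head(unknown, 5), collapse = ", "))
  isoform_id <- sample_id <- offset <- count <- L <- NULL
  dt[, L := utrs$length_L[match(isoform_id, utrs$isoform_id)]]
  if (dt[, any(offset < 0 | offset >= L)])
    stop("ncom_table: offsets outside [0, L) for some isoform")
  agg <- dt[, .(ncom = sum(count * (offset + 0.5)) / sum(count) / L[1L],
                total = sum(count)),
            by = .(isoform_id, sample_id)]
  samples <- sort(unique(meta$sample_id[meta$layer == "ncom"]))
  if (!length(samples)) samples <- sort(unique(agg$sample_id))
  m <- matrix(NA_real_, nrow = nrow(utrs), ncol = length(samples),
              dimnames = list(utrs$isoform_id, samples))
  m[cbind(match(agg$isoform_id, utrs$isoform_id),
          match(agg$sample_id, samples))] <- agg$ncom
  n_na <- sum(is.na(m))
  if (n_na) ct_log("apa", "%d isoform x sample cells with zero coverage (NA NCOM)", n_na)
  feature_table(m, meta, "ncom")
}

#' Call polyadenylation sites by scanning windows
#'
#' Tiles the UTR (plus up to `cfg$pas_max_extension_nt` beyond the annotated
#' end) into consecutive windows of `cfg$pas_window_nt` nucleotides. A window
#' is called when its summed count reaches
#' `max(cfg$pas_min_abs_count, cfg$pas_min_frac * total)`; adjacent
#' qualifying windows are merged into one call. Calls lying entirely past the
#' annotated end are flagged `is_extension`.
#'
#' @param positions,counts read profile; offsets may exceed the annotated
#'   length (up to the extension bound).
#' @param length_L annotated UTR length.
#' @param cfg `run_config`.
#' @return data.frame of PAS calls: `window_start`, `window_end`, `score`
#'   (summed count), `is_extension`. Zero rows for an empty profile.
#' @export
call_pas <- function(positions, counts, length_L, cfg = run_config()) {
  if (length(positions) != length(counts))
    stop("call_pas: positions and counts lengths differ")
  empty <- data.frame(window_start = integer(0), window_end = integer(0),
                      score = numeric(0), is_extension = logical(0))
  if (!length(positions) || sum(counts) == 0) return(empty)
  max_off <- length_L + cfg$pas_max_extension_nt
  if (any(positions < 0 | positions >= max_off))
    stop("call_pas: positions beyond the extension bound (",
         cfg$pas_max_extension_nt, " nt past the annotated end)")
  total <- sum(counts)
  w <- cfg$pas_window_nt
  win <- positions %/% w
  score <- tapply(counts, win, sum)
  widx <- as.integer(names(score))
  thr <- max(cfg$pas_min_abs_count, cfg$pas_min_frac * total)
  keep <- score >= thr
  if (!any(keep)) return(empty)
  widx <- widx[keep]
  score <- score[keep]
  ord <- order(widx)
  widx <- widx[ord]; score <- score[ord]
  # merge runs of adjacent qualifying windows
  grp <- cumsum(c(1L, diff(widx) > 1L))
  out <- do.call(rbind, lapply(split(seq_along(widx), grp), function(ii) {
    ws <- widx[ii[1L]] * w
    we <- (widx[ii[length(ii)]] + 1L) * w
    we <- min(we, max_off)
    data.frame(window_start = as.integer(ws), window_end = as.integer(we),
               score = sum(score[ii]),
               is_extension = ws >= length_L)
  }))
  rownames(out) <- NULL
  out
}

#' Extend a UTR annotation by discovered downstream PASs
#'
#' If any call is flagged `is_extension`, the UTR end moves to the distal
#' edge of the farthest extension call and the isoform id gains the suffix
#' "_ext"; otherwise the input is returned unchanged. Calls are bounded by
#' the config, so extensions never exceed `pas_max_extension_nt`.
#'
#' @param utr one-row UTR model (see [utr_model()]).
#' @param calls data.frame from [call_pas()].
#' @return UTR model, possibly extended.
#' @export
extend_annotation <- function(utr, calls) {
  if (!nrow(calls) || !any(calls$is_extension)) return(utr)
  new_len <- max(calls$window_end[calls$is_extension])
  utr_model(utr$gene, paste0(utr$isoform_id, "_ext"), utr$chrom, utr$strand,
            utr$utr_start, utr$utr_start + new_len)
}

#' Merge transcript isoforms with identical 3' UTRs
#'
#' Isoforms of one gene sharing `(chrom, strand, utr_start, utr_end)` are
#' collapsed into a single record; their ids are concatenated with "|" and
#' their counts summed. Idempotent.
#'
#' @param utrs data.frame of UTR models.
#' @param counts numeric vector of per-isoform counts (parallel to `utrs`).
#' @return list with merged `utrs` and `counts`.
#' @export
merge_identical_utrs <- function(utrs, counts) {
  stopifnot(nrow(utrs) == length(counts))
  key <- paste(utrs$gene, utrs$chrom, utrs$strand, utrs$utr_start,
               utrs$utr_end, sep = "\r")
  idx <- split(seq_len(nrow(utrs)), key)
  rows <- lapply(idx, function(ii) {
    u <- utrs[ii[1L], , drop = FALSE]
    ids <- sort(unique(unlist(strsplit(utrs$isoform_id[ii], "|", fixed = TRUE))))
    u$isoform_id <- paste(ids, collapse = "|")
    u
  })
  ord <- order(vapply(idx, min, 1L))
  merged <- do.call(rbind, rows[ord])
  rownames(merged) <- NULL
  list(utrs = merged,
       counts = vapply(idx[ord], function(ii) sum(counts[ii]), numeric(1)))
}

#' Median-of-ratios size factors
#'
#' For each sample j the size factor is the median over features of
#' `count_ij / geometric_mean_i(counts)`, restricted to features positive in
#' all samples. Dividing a count matrix by its size factors equalizes
#' sequencing depth while being robust to differentially expressed features.
#'
#' @param counts numeric matrix, features x samples.
#' @return numeric vector of per-sample factors (named by column).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("size_factors: need at least 2 samples")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("size_factors: no feature positive in all samples")
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  apply(lc, 2L, function(col) exp(median(col - geo)))
}

#' Normalize a count matrix by its size factors
#' @param counts features x samples count matrix.
#' @return matrix of normalized counts.
#' @export
normalize_counts <- function(counts) {
  sf <- size_factors(counts)
  sweep(as.matrix(counts), 2L, sf, "/")
}

#' Distal PAS usage ratio
#'
#' Ratio of long-3'-UTR (distal isoform) expression to total gene expression.
#' Ratios above 1 (possible with noisy expression estimates) are kept as raw
#' values but flagged.
#'
#' @param long_expr expression of the long-3'-UTR isoform.
#' @param total_expr total gene expression; must be positive.
#' @return data.frame with `ratio` and `flag_gt1`.
#' @export
distal_usage <- function(long_expr, total_expr) {
  if (any(total_expr <= 0)) stop("distal_usage: total_expr must be positive")
  r <- long_expr / total_expr
  if (any(r > 1))
    ct_log("apa", "%d distal-usage ratio(s) exceed 1 (flagged, kept raw)", sum(r > 1))
  data.frame(ratio = r, flag_gt1 = r > 1)
}
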