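#' Per-base FPKM from depth
#'
#' Treats every base as a 1-bp feature, so
#' `fpkm[i] = depth[i] / (0.001 kb * total_mapped_reads/1e6)
#'          = depth[i] * 1e9 / total_mapped_reads`.
#' This is the only length-consistent reading of FPKM at single-base
#' resolution; the peak threshold is configurable so other conventions can
#' be matched by rescaling.
#'
#' @param depth Per-base depth vector.
#' @param total_mapped_reads Library size in reads (> 0).
#' @return Numeric per-base FPKM vector.
#' @export
per_base_fpkm <- function(depth, total_mapped_reads) {
  stopifnot(total_mapped_reads > 0)
  depth * 1e9 / total_mapped_reads
}

#' Consensus peak-calling parameters
#'
#' Defaults encode the published rule: a peak is a continuous run of more
#' than 150 bp with per-base FPKM strictly above 100 in every replicate
#' (four replicates in the source analysis); valleys are the complementary
#' runs at or below the threshold. The short/long 3'UTR cutoffs feed the
#' pattern-type rules and have no published value.
#'
#' @param fpkm_threshold Strict per-base FPKM bound (default 100).
#' @param min_run_bp Minimum run length in bp; 151 encodes strictly >150.
#' @param min_replicates Replicates that must pass per base; `NULL` (default)
#'   means all supplied replicates.
#' @param short_utr_max_bp,long_utr_min_bp 3'UTR length cutoffs for pattern
#'   types ii / iii (defaults 1000 / 2000).
#' @param consensus `"base"` (default) requires the threshold at the same
#'   bases across replicates before run-length filtering; `"interval"` calls
#'   runs per replicate first and intersects the resulting peak bases.
#' @return A `PeakParams` list.
#' @export
peak_params <- function(fpkm_threshold = 100, min_run_bp = 151L,
                        min_replicates = NULL, short_utr_max_bp = 1000L,
                        long_utr_min_bp = 2000L,
                        consensus = c("base", "interval")) {
  stopifnot(fpkm_threshold > 0, min_run_bp >= 1)
  structure(list(fpkm_threshold = fpkm_threshold,
                 min_run_bp = as.integer(min_run_bp),
                 min_replicates = min_replicates,
                 short_utr_max_bp = as.integer(short_utr_max_bp),
                 long_utr_min_bp = as.integer(long_utr_min_bp),
                 consensus = match.arg(consensus)),
            class = "PeakParams")
}

.as_fpkm_matrix <- function(fpkm) {
  if (is.list(fpkm)) {
    lens <- lengths(fpkm)
    if (length(unique(lens)) != 1L)
      stop("replicate FPKM arrays must all have the same length")
    fpkm <- do.call(cbind, fpkm)
  }
  if (is.vector(fpkm)) fpkm <- matrix(fpkm, ncol = 1L)
  fpkm
}

# Maximal TRUE runs of length >= min_run; BED-style offsets within the array
.runs <- function(ok, min_run) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

.min_reps <- function(params, n_rep) {
  mr <- if (is.null(params$min_replicates)) n_rep else params$min_replicates
  if (mr < 1 || mr > n_rep) stop("min_replicates must be in 1..n_replicates")
  mr
}

#' Call consensus peaks across replicates
#'
#' Computes the base set where FPKM exceeds the threshold in at least
#' `min_replicates` replicates (default: all), then returns the maximal runs
#' of that set longer than `min_run_bp - 1` bases. With
#' `consensus = "interval"`, per-replicate runs are length-filtered first and
#' their base sets intersected before the final run filter.
#'
#' @param fpkm One per-base FPKM array per replicate: a list of equal-length
#'   vectors or a bases-by-replicates matrix.
#' @param params A [peak_params()].
#' @return `data.frame` of peaks with BED-style `start`/`end` offsets within
#'   the array, `length`, `n_supporting_replicates`, and a `mean_fpkm`
#'   matrix attribute (peaks x replicates).
#' @export
call_consensus_peaks <- function(fpkm, params = peak_params()) {
  fpkm <- .as_fpkm_matrix(fpkm)
  if (nrow(fpkm) == 0L) return(.empty_peaks())
  mr <- .min_reps(params, ncol(fpkm))
  above <- fpkm > params$fpkm_threshold
  ok <- if (params$consensus == "base") {
    rowSums(above) >= mr
  } else {
    inruns <- apply(above, 2L, function(col) {
      runs <- .runs(col, params$min_run_bp)
      v <- logical(length(col))
      for (i in seq_len(nrow(runs))) v[(runs$start[i] + 1L):runs$end[i]] <- TRUE
      v
    })
    rowSums(matrix(inruns, nrow = nrow(fpkm))) >= mr
  }
  peaks <- .runs(ok, params$min_run_bp)
  if (nrow(peaks) == 0L) return(.empty_peaks())
  mean_fpkm <- t(vapply(seq_len(nrow(peaks)), function(i) {
    colMeans(fpkm[(peaks$start[i] + 1L):peaks$end[i], , drop = FALSE])
  }, numeric(ncol(fpkm))))
  peaks$n_supporting_replicates <- vapply(seq_len(nrow(peaks)), function(i) {
    sum(apply(above[(peaks$start[i] + 1L):peaks$end[i], , drop = FALSE], 2L, all))
  }, integer(1))
  attr(peaks, "mean_fpkm") <- mean_fpkm
  peaks
}

.empty_peaks <- function() {
  p <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                  n_supporting_replicates = integer(0))
  attr(p, "mean_fpkm") <- matrix(numeric(0), nrow = 0, ncol = 0)
  p
}

#' Call consensus valleys
#'
#' Maximal runs longer than `min_run_bp - 1` bases where FPKM is at or below
#' the threshold (the complement of the strict peak inequality, so peak and
#' valley base sets partition the decided bases) in at least
#' `min_replicates` replicates. Call this on 3'UTR arrays only: valleys are
#' defined within the annotated 3'UTR.
#'
#' @inheritParams call_consensus_peaks
#' @return `data.frame` of valleys with `start`, `end`, `length`.
#' @export
call_valleys <- function(fpkm, params = peak_params()) {
  fpkm <- .as_fpkm_matrix(fpkm)
  if (nrow(fpkm) == 0L) return(data.frame(start = integer(0), end = integer(0),
                                          length = integer(0)))
  mr <- .min_reps(params, ncol(fpkm))
  ok <- rowSums(fpkm <= params$fpkm_threshold) >= mr
  .runs(ok, params$min_run_bp)
}

#' Classify a gene's 3'UTR peak architecture
#'
#' Three archetypes are distinguished, after peak calling on the
#' concatenated transcript-oriented CDS+3'UTR arrays:
#' * `TYPE_I` — two or more peaks entirely inside the 3'UTR with at least
#'   one valley between consecutive peaks (discrete internal 3'UTR peaks).
#' * `TYPE_II` — a single peak overlapping the 3'UTR that begins within
#'   50 bp of the junction on the CDS side (or abuts it), with a short 3'UTR
#'   (`<= short_utr_max_bp`): expression runs continuously off the CDS end.
#' * `TYPE_III` — a long 3'UTR (`>= long_utr_min_bp`) with at least one peak
#'   and any above-threshold CDS coverage confined to a terminal run of at
#'   most 25% of the CDS length adjacent to the junction (short leading CDS
#'   stretch).
#' * `UNCLASSIFIED` otherwise.
#'
#' @param cds_fpkm,utr_fpkm Per-base FPKM arrays (list or matrix), CDS and
#'   spliced 3'UTR, transcript-oriented.
#' @param params A [peak_params()].
#' @return List with `pattern_type`, `rule_trace` (human-readable decision
#'   trace), `utr_peaks`, `utr_valleys` (3'UTR-relative BED-style offsets)
#'   and `full_peaks` (offsets within CDS+3'UTR).
#' @export
classify_pattern <- function(cds_fpkm, utr_fpkm, params = peak_params()) {
  cds_fpkm <- .as_fpkm_matrix(cds_fpkm); utr_fpkm <- .as_fpkm_matrix(utr_fpkm)
  if (ncol(cds_fpkm) != ncol(utr_fpkm))
    stop("CDS and 3'UTR arrays must have the same number of replicates")
  Lc <- nrow(cds_fpkm); Lu <- nrow(utr_fpkm)
  full <- rbind(cds_fpkm, utr_fpkm)
  full_peaks <- call_consensus_peaks(full, params)
  utr_peaks <- call_consensus_peaks(utr_fpkm, params)
  valleys <- call_valleys(utr_fpkm, params)

  internal <- full_peaks[full_peaks$start >= Lc, , drop = FALSE]
  overlapping_utr <- full_peaks[full_peaks$end > Lc, , drop = FALSE]

  valley_between <- FALSE
  if (nrow(utr_peaks) >= 2L && nrow(valleys) >= 1L) {
    for (i in seq_len(nrow(utr_peaks) - 1L)) {
      gap_s <- utr_peaks$end[i]; gap_e <- utr_peaks$start[i + 1L]
      if (any(valleys$start >= gap_s & valleys$end <= gap_e)) valley_between <- TRUE
    }
  }

  mr <- .min_reps(params, ncol(cds_fpkm))
  cds_above <- which(rowSums(cds_fpkm > params$fpkm_threshold) >= mr)
  cds_confined <- length(cds_above) == 0L ||
    all(cds_above > Lc - ceiling(0.25 * Lc))

  type <- if (nrow(internal) >= 2L && valley_between) {
    "TYPE_I"
  } else if (nrow(overlapping_utr) == 1L &&
             overlapping_utr$start[1] >= Lc - 50L &&
             overlapping_utr$start[1] <= Lc &&
             Lu <= params$short_utr_max_bp) {
    "TYPE_II"
  } else if (Lu >= params$long_utr_min_bp && nrow(overlapping_utr) >= 1L &&
             cds_confined) {
    "TYPE_III"
  } else {
    "UNCLASSIFIED"
  }
  trace <- sprintf(
    "n_full_peaks=%d;n_internal_utr_peaks=%d;n_peaks_overlapping_utr=%d;valley_between=%s;utr_len=%d;cds_len=%d;cds_above_confined=%s",
    nrow(full_peaks), nrow(internal), nrow(overlapping_utr), valley_between,
    Lu, Lc, cds_confined)
  list(pattern_type = type, rule_trace = trace,
       utr_peaks = utr_peaks, utr_valleys = valleys, full_peaks = full_peaks)
}

#' Bundle peaks, valleys and the pattern call for one gene
#' @param gene_id Gene id.
#' @param pattern Output of [classify_pattern()].
#' @return A `PeakSet` list.
#' @export
peak_set <- function(gene_id, pattern) {
  structure(list(gene_id = gene_id, peaks = pattern$utr_peaks,
                 valleys = pattern$utr_valleys,
                 pattern_type = pattern$pattern_type,
                 rule_trace = pattern$rule_trace), class = "PeakSet")
}

#' Project spliced-3'UTR peak offsets to genomic intervals
#' @param model A [gene_model()].
#' @param intervals `data.frame` with `start`/`end` BED-style offsets within
#'   the spliced 3'UTR (peaks or valleys).
#' @return `GRangesList`, one element per interval.
#' @export
project_to_genomic <- function(model, intervals) {
  out <- lapply(seq_len(nrow(intervals)), function(i)
    spliced_to_genomic(model, intervals$start[i], intervals$end[i]))
  GenomicRanges::GRangesList(out)
}

#' Write peak/valley calls as BED6
#' @param models Named list of gene models.
#' @param peaksets Named list of `PeakSet`s (same genes).
#' @param what `"peaks"` or `"valleys"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(models, peaksets, what = c("peaks", "valleys"), path) {
  what <- match.arg(what)
  rows <- list()
  for (gid in names(peaksets)) {
    ps <- peaksets[[gid]]; m <- models[[gid]]
    iv <- ps[[what]]
    if (is.null(iv) || nrow(iv) == 0L) next
    mean_fpkm <- attr(iv, "mean_fpkm")
    for (i in seq_len(nrow(iv))) {
      grl <- spliced_to_genomic(m, iv$start[i], iv$end[i])
      score <- if (!is.null(mean_fpkm) && nrow(mean_fpkm) >= i)
        round(mean(mean_fpkm[i, ]), 2) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = m$chrom, start = GenomicRanges::start(grl) - 1L,
        end = GenomicRanges::end(grl),
        name = sprintf("%s|%s%d", gid, if (what == "peaks") "peak" else "valley", i),
        score = score, strand = m$strand)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), score = numeric(0), strand = character(0))
  df <- df[order(df$chrom, df$start), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
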