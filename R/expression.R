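#' Normalized region expression
#'
#' Expression of a CDS or 3'UTR region, as reads per effective kilobase per
#' million total mapped reads:
#' `read_count / ((effective_length_bp/1000) * (total_mapped_reads/1e6))`.
#' The effective length is the number of bases in the region with non-zero
#' coverage. A region with zero reads has expression 0 by definition,
#' whatever its effective length.
#'
#' @param read_count Reads assigned to the region (vectorised).
#' @param effective_length_bp Bases with non-zero coverage.
#' @param total_mapped_reads Library size in reads (> 0).
#' @return Numeric expression values.
#' @export
normalized_expression <- function(read_count, effective_length_bp, total_mapped_reads) {
  stopifnot(all(total_mapped_reads > 0), all(read_count >= 0),
            all(effective_length_bp >= 0))
  if (any(read_count > 0 & effective_length_bp == 0))
    stop("impossible state: reads assigned to a region with zero covered bases")
  out <- ifelse(read_count == 0, 0,
                read_count / ((effective_length_bp / 1000) * (total_mapped_reads / 1e6)))
  as.numeric(out)
}

#' Effective length of a region: bases with non-zero depth
#' @param depth Per-base depth vector.
#' @return Integer count of covered bases.
#' @export
effective_length <- function(depth) sum(depth > 0)

#' Expressed-gene filter
#'
#' A gene is expressed when its total assigned reads reach `min_reads`
#' (default 5). The total counts each read once: junction-straddling reads
#' appear in both per-region counts, so their number is subtracted.
#'
#' @param read_count_cds,read_count_utr Per-region read counts.
#' @param n_straddling Reads overlapping both regions (counted in both).
#' @param min_reads Threshold (default 5, inclusive).
#' @return Logical.
#' @export
is_expressed <- function(read_count_cds, read_count_utr, n_straddling = 0L,
                         min_reads = 5L) {
  stopifnot(all(read_count_cds >= 0), all(read_count_utr >= 0))
  (read_count_cds + read_count_utr - n_straddling) >= min_reads
}

#' Quantify CDS and 3'UTR expression for a set of genes
#'
#' Runs [region_coverage()] for both regions of every gene against one
#' replicate's coverage source and assembles the long per-gene-region table.
#'
#' @inheritParams region_coverage
#' @param models Named list of [gene_model()]s.
#' @param total_mapped_reads Library size of the replicate.
#' @param replicate_id Replicate label recorded in the output.
#' @param keep_depth Attach the per-gene depth arrays as attribute
#'   `"tracks"` (used by the peak-calling stage to avoid re-reading).
#' @return `data.frame` with columns `replicate_id`, `gene_id`, `region`,
#'   `read_count`, `region_length_bp`, `effective_length_bp`, `sum_depth`,
#'   `expression`, `gene_read_count`.
#' @export
quantify_regions <- function(models, x, total_mapped_reads, replicate_id = "rep1",
                             min_mapq = 20L, counts = NULL, keep_depth = FALSE) {
  src <- .coverage_source(x, min_mapq)
  rows <- list(); tracks <- list()
  for (m in models) {
    tr <- coverage_track(src$value, m, replicate_id, total_mapped_reads,
                         min_mapq, counts)
    if (keep_depth) tracks[[m$gene_id]] <- tr
    for (region in c("CDS", "UTR3")) {
      rc <- tr[[if (region == "CDS") "cds" else "utr3"]]
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_id = replicate_id, gene_id = m$gene_id, region = region,
        read_count = rc$read_count,
        region_length_bp = length(rc$depth),
        effective_length_bp = rc$effective_length_bp,
        sum_depth = sum(rc$depth),
        expression = normalized_expression(rc$read_count, rc$effective_length_bp,
                                           total_mapped_reads),
        gene_read_count = tr$gene_read_count)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_depth) attr(out, "tracks") <- tracks
  out
}

#' Write a quantification table as TSV
#' @param quant Output of [quantify_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(quant, path) {
  utils::write.table(quant, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
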