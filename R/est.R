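# EST / cDNA-fragment classification against a gene model.
#
# The junction base itself (the first base 3' of the stop-codon boundary)
# belongs to the 3'UTR side: a fragment ending exactly at the junction has
# zero CDS-side overlap beyond it and is not junction-spanning.

.as_fragment_granges <- function(fragments, chrom) {
  if (methods::is(fragments, "GRanges")) return(fragments)
  if (is.data.frame(fragments) && all(c("start", "end") %in% names(fragments))) {
    return(GenomicRanges::GRanges(chrom, bed_to_iranges(fragments$start, fragments$end)))
  }
  stop("fragments must be a GRanges or a BED-style data.frame(start, end)")
}

# bp of overlap between each fragment and an interval set
.overlap_bp <- function(frags, ir, chrom) {
  gr <- GenomicRanges::GRanges(chrom, ir)
  hits <- GenomicRanges::findOverlaps(frags, gr, ignore.strand = TRUE)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(frags)[S4Vectors::queryHits(hits)],
    IRanges::ranges(gr)[S4Vectors::subjectHits(hits)]))
  out <- numeric(length(frags))
  if (length(hits)) {
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' Classify fragments as 3'UTR-only, CDS-only, junction-spanning or outside
#'
#' A fragment is `MIXED` when it overlaps both the CDS and the 3'UTR by at
#' least `min_overlap_bp`; `UTR_ONLY`/`CDS_ONLY` when it reaches that
#' overlap in exactly one region; `OUTSIDE` otherwise.
#'
#' @param fragments `GRanges`, or BED-style `data.frame(start, end)` taken to
#'   be on the model's chromosome.
#' @param model A [gene_model()].
#' @param min_overlap_bp Minimum overlap to count a region (default 1).
#' @return Factor with levels `UTR_ONLY`, `CDS_ONLY`, `MIXED`, `OUTSIDE`.
#' @export
classify_fragments <- function(fragments, model, min_overlap_bp = 1L) {
  frags <- .as_fragment_granges(fragments, model$chrom)
  on_chrom <- as.character(GenomicRanges::seqnames(frags)) == model$chrom
  utr_bp <- cds_bp <- numeric(length(frags))
  utr_bp[on_chrom] <- .overlap_bp(frags[on_chrom], model$utr3, model$chrom)
  cds_bp[on_chrom] <- .overlap_bp(frags[on_chrom], model$cds, model$chrom)
  u <- utr_bp >= min_overlap_bp; c_ <- cds_bp >= min_overlap_bp
  out <- ifelse(u & c_, "MIXED",
         ifelse(u, "UTR_ONLY", ifelse(c_, "CDS_ONLY", "OUTSIDE")))
  factor(out, levels = c("UTR_ONLY", "CDS_ONLY", "MIXED", "OUTSIDE"))
}

#' Summarise an EST set against one gene
#'
#' Counts and fractions of 3'UTR-only, CDS-only and junction-spanning
#' (mixed) fragments — fragments overlapping neither region are excluded
#' from the denominator and reported separately — plus the fraction of
#' fragments overlapping each `bin_size`-bp bin around the CDS-3'UTR
#' junction, and (when a `PeakSet` is supplied) the number of fragments
#' whose span covers an entire internal 3'UTR valley.
#'
#' @inheritParams classify_fragments
#' @param peakset Optional [peak_set()] for the valley-spanning count.
#' @param bin_size,n_bins Junction-bin profile geometry (default 250 bp x 4
#'   bins each side).
#' @return List with `summary` (one-row `data.frame`), `bins`
#'   (`data.frame` of `offset`, `n_overlapping`, `fraction`), and `classes`
#'   (per-fragment labels).
#' @export
summarize_ests <- function(fragments, model, peakset = NULL, bin_size = 250L,
                           n_bins = 4L, min_overlap_bp = 1L) {
  frags <- .as_fragment_granges(fragments, model$chrom)
  cls <- classify_fragments(frags, model, min_overlap_bp)
  inside <- cls != "OUTSIDE"
  n_total <- sum(inside)
  n_utr <- sum(cls == "UTR_ONLY"); n_cds <- sum(cls == "CDS_ONLY")
  n_mix <- sum(cls == "MIXED")

  bins <- junction_flank(model, bin_size, n_bins)
  bin_gr <- GenomicRanges::GRanges(bins$chrom, bed_to_iranges(bins$start, bins$end))
  n_ov <- GenomicRanges::countOverlaps(bin_gr, frags[inside], ignore.strand = TRUE)
  bins$n_overlapping <- n_ov
  bins$fraction <- if (n_total > 0) n_ov / n_total else NA_real_

  n_span <- NA_integer_
  if (!is.null(peakset)) {
    n_span <- 0L
    pk <- peakset$peaks; vl <- peakset$valleys
    if (!is.null(vl) && nrow(vl) > 0L && !is.null(pk) && nrow(pk) >= 2L) {
      internal <- vl[vapply(seq_len(nrow(vl)), function(i)
        any(pk$end <= vl$start[i]) && any(pk$start >= vl$end[i]), logical(1)), ,
        drop = FALSE]
      if (nrow(internal) > 0L) {
        covered <- rep(FALSE, length(frags))
        for (i in seq_len(nrow(internal))) {
          g <- spliced_to_genomic(model, internal$start[i], internal$end[i])
          vs <- min(GenomicRanges::start(g)); ve <- max(GenomicRanges::end(g))
          covered <- covered |
            (GenomicRanges::start(frags) <= vs & GenomicRanges::end(frags) >= ve &
             as.character(GenomicRanges::seqnames(frags)) == model$chrom)
        }
        n_span <- sum(covered & inside)
      }
    }
  }

  summary <- data.frame(
    gene_id = model$gene_id, n_total = n_total, n_outside = sum(!inside),
    n_utr_only = n_utr, n_cds_only = n_cds, n_mixed = n_mix,
    frac_utr_only = if (n_total > 0) n_utr / n_total else NA_real_,
    frac_cds_only = if (n_total > 0) n_cds / n_total else NA_real_,
    frac_mixed = if (n_total > 0) n_mix / n_total else NA_real_,
    n_spanning_internal_valley = n_span)
  list(summary = summary, bins = bins, classes = cls)
}
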