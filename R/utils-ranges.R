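# Coordinate conventions
#
# In-memory interval objects are IRanges/GRanges (1-based, closed), the
# Bioconductor convention, so that all overlap and coverage arithmetic goes
# through IRanges/GenomicRanges. Everything that crosses a flat-file boundary
# (BED/bedGraph output tables, the `junction` coordinate, peak offsets) is
# BED-style: 0-based start, exclusive end. These two helpers are the only
# place the conversion happens.

bed_to_iranges <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("interval start must be < end (BED-style coordinates)")
  IRanges::IRanges(start = start + 1L, end = end)
}

iranges_to_bed <- function(x) {
  data.frame(start = IRanges::start(x) - 1L, end = IRanges::end(x))
}

# Accept either an IRanges or a BED-style data.frame(start, end)
as_region_iranges <- function(x) {
  if (methods::is(x, "IRanges")) return(x)
  if (is.data.frame(x) && all(c("start", "end") %in% names(x))) {
    return(bed_to_iranges(x$start, x$end))
  }
  stop("regions must be an IRanges or a data.frame with BED-style start/end")
}

# 3'UTR intervals in transcript (5'->3') order
utr_intervals_tx <- function(model) {
  ir <- model$utr3
  if (model$strand == "+") {
    ir[order(IRanges::start(ir))]
  } else {
    ir[order(IRanges::end(ir), decreasing = TRUE)]
  }
}

#' Total 3'UTR length of a gene model (bp)
#' @param model A [gene_model()].
#' @return Integer length.
#' @export
utr3_length <- function(model) sum(IRanges::width(model$utr3))

#' Total CDS length of a gene model (bp)
#' @param model A [gene_model()].
#' @return Integer length.
#' @export
cds_length <- function(model) sum(IRanges::width(model$cds))

#' Genomic span of a gene model (CDS union 3'UTR), BED-style
#' @param model A [gene_model()].
#' @return Named vector `c(start, end)`, 0-based half-open.
#' @export
gene_span <- function(model) {
  all <- c(model$cds, model$utr3)
  c(start = min(IRanges::start(all)) - 1L, end = max(IRanges::end(all)))
}

# Map an interval [start0, end) on the spliced (transcript-oriented,
# 0-based from the junction) 3'UTR to genomic GRanges.
spliced_to_genomic <- function(model, start0, end) {
  stopifnot(start0 >= 0, end > start0)
  ir <- utr_intervals_tx(model)
  w <- IRanges::width(ir)
  offs <- cumsum(c(0L, w))          # spliced offset at which each interval begins
  total <- offs[length(offs)]
  if (end > total) stop("spliced interval extends past the 3'UTR length")
  out <- list()
  for (i in seq_along(ir)) {
    lo <- max(start0, offs[i]); hi <- min(end, offs[i + 1L])
    if (lo >= hi) next
    within_s <- lo - offs[i]; within_e <- hi - offs[i]   # 0-based within interval
    if (model$strand == "+") {
      gs <- IRanges::start(ir[i]) + within_s
      ge <- IRanges::start(ir[i]) + within_e - 1L
    } else {
      ge <- IRanges::end(ir[i]) - within_s
      gs <- IRanges::end(ir[i]) - within_e + 1L
    }
    out[[length(out) + 1L]] <- c(gs, ge)
  }
  m <- do.call(rbind, out)
  GenomicRanges::GRanges(model$chrom,
                         IRanges::IRanges(m[, 1], m[, 2]),
                         strand = model$strand)
}
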