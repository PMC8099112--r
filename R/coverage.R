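# Per-base coverage and per-region read counts from BAM or bedGraph.
#
# The BAM path counts alignment records (primary alignments passing the MAPQ
# filter), one per read; coverage comes from the aligned blocks. The bedGraph
# path reconstructs per-base depth exactly, but depth alone cannot recover
# read counts, so a companion per-region count table is required.

#' Read primary alignments from a BAM file
#'
#' @param path Coordinate-sorted, indexed BAM.
#' @param min_mapq Minimum mapping quality (default 20).
#' @param which Optional `GRanges` restriction.
#' @return A `GAlignments` object; warns when no alignment passes the filter.
#' @export
read_alignments <- function(path, min_mapq = 20L, which = NULL) {
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- if (is.null(which)) {
    Rsamtools::ScanBamParam(flag = flags, mapqFilter = min_mapq)
  } else {
    Rsamtools::ScanBamParam(flag = flags, mapqFilter = min_mapq, which = which)
  }
  aln <- GenomicAlignments::readGAlignments(Rsamtools::BamFile(path), param = param)
  if (length(aln) == 0L)
    warning("no alignments pass the filter in ", path, "; coverage will be all zero")
  aln
}

#' Total mapped reads (library size) of a BAM file
#' @inheritParams read_alignments
#' @return Number of primary mapped records with MAPQ >= `min_mapq`.
#' @export
total_mapped_reads_bam <- function(path, min_mapq = 20L) {
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, mapqFilter = min_mapq)
  Rsamtools::countBam(path, param = param)$records
}

#' Per-base coverage from a bedGraph file
#' @param path bedGraph path (column 4 = depth).
#' @return A per-chromosome `RleList` of integer depth.
#' @export
read_bedgraph_coverage <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomicRanges::coverage(gr, weight = "score")
}

# Normalise the coverage source: returns list(kind = "reads"|"cov", value)
.coverage_source <- function(x, min_mapq) {
  if (methods::is(x, "GAlignments")) return(list(kind = "reads", value = x))
  if (methods::is(x, "RleList") || methods::is(x, "SimpleRleList"))
    return(list(kind = "cov", value = x))
  if (is.character(x) && length(x) == 1L) {
    ext <- tolower(tools::file_ext(x))
    if (ext == "bam") return(list(kind = "reads", value = read_alignments(x, min_mapq)))
    return(list(kind = "cov", value = read_bedgraph_coverage(x)))
  }
  stop("coverage source must be a BAM path, GAlignments, bedGraph path or RleList")
}

# Depth over `ir` on chromosome `chrom`, transcript-oriented
.depth_tx <- function(cov, chrom, ir, strand) {
  if (!chrom %in% names(cov))
    stop("chromosome '", chrom, "' not present in the coverage input")
  rle <- cov[[chrom]]
  need <- max(IRanges::end(ir))
  if (length(rle) < need) rle <- c(rle, S4Vectors::Rle(0L, need - length(rle)))
  ir <- ir[order(IRanges::start(ir))]
  depth <- unlist(lapply(seq_along(ir), function(i)
    as.numeric(S4Vectors::window(rle, IRanges::start(ir)[i], IRanges::end(ir)[i]))),
    use.names = FALSE)
  if (strand == "-") depth <- rev(depth)
  depth
}

.region_ranges <- function(model, region) {
  switch(region, CDS = model$cds, UTR3 = model$utr3,
         stop("region must be 'CDS' or 'UTR3'"))
}

.counts_lookup <- function(counts, gene_id, region) {
  if (is.null(counts))
    stop("bedGraph/coverage input needs a per-region read-count table (gene_id, region, read_count)")
  hit <- counts$read_count[counts$gene_id == gene_id & counts$region == region]
  if (length(hit) != 1L)
    stop("count table has no unique entry for ", gene_id, " / ", region)
  as.numeric(hit)
}

#' Per-base depth and read count for one gene region
#'
#' A read overlapping the region by at least 1 bp is assigned to it; a read
#' overlapping both CDS and 3'UTR is therefore counted once in each region's
#' count, matching independent per-region coverage counting.
#'
#' @param x Coverage source: BAM path, `GAlignments`, bedGraph path, or a
#'   depth `RleList`.
#' @param model A [gene_model()].
#' @param region `"UTR3"` or `"CDS"`.
#' @param min_mapq MAPQ filter applied when `x` is a BAM path (default 20).
#' @param counts Per-region read-count table (`gene_id`, `region`,
#'   `read_count`) — required for bedGraph/`RleList` sources.
#' @return List with `depth` (transcript-oriented numeric vector over the
#'   region), `read_count`, and `effective_length_bp` (bases with depth > 0).
#' @export
region_coverage <- function(x, model, region = c("UTR3", "CDS"),
                            min_mapq = 20L, counts = NULL) {
  region <- match.arg(region)
  src <- .coverage_source(x, min_mapq)
  ir <- .region_ranges(model, region)
  if (src$kind == "reads") {
    reads <- src$value
    chroms <- GenomeInfoDb::seqlevels(reads)
    if (length(chroms) && !model$chrom %in% chroms)
      stop("chromosome '", model$chrom, "' not present in the coverage input")
    gr <- GenomicRanges::GRanges(model$chrom, ir)
    cov <- GenomicRanges::coverage(reads)
    if (!model$chrom %in% names(cov))
      cov[[model$chrom]] <- S4Vectors::Rle(0L, max(IRanges::end(ir)))
    depth <- .depth_tx(cov, model$chrom, ir, model$strand)
    read_count <- sum(IRanges::overlapsAny(reads, gr, ignore.strand = TRUE))
  } else {
    depth <- .depth_tx(src$value, model$chrom, ir, model$strand)
    read_count <- .counts_lookup(counts, model$gene_id, region)
  }
  list(depth = depth, read_count = read_count,
       effective_length_bp = sum(depth > 0))
}

#' Gene-level read count (junction-straddling reads counted once)
#'
#' @inheritParams region_coverage
#' @return Number of reads overlapping the CDS or the 3'UTR; from the count
#'   table (`region == "GENE"`) for coverage-only sources.
#' @export
gene_read_count <- function(x, model, min_mapq = 20L, counts = NULL) {
  src <- .coverage_source(x, min_mapq)
  if (src$kind == "reads") {
    gr <- GenomicRanges::GRanges(model$chrom, c(model$cds, model$utr3))
    sum(IRanges::overlapsAny(src$value, gr, ignore.strand = TRUE))
  } else {
    .counts_lookup(counts, model$gene_id, "GENE")
  }
}

#' Assemble the per-replicate coverage track of one gene
#'
#' @inheritParams region_coverage
#' @param replicate_id Replicate label.
#' @param total_mapped_reads Library size (total mapped reads) of the replicate.
#' @return A `CoverageTrack`: list with per-region `depth`/`read_count`,
#'   the gene-level read count, and `total_mapped_reads`.
#' @export
coverage_track <- function(x, model, replicate_id, total_mapped_reads,
                           min_mapq = 20L, counts = NULL) {
  stopifnot(total_mapped_reads > 0)
  src <- .coverage_source(x, min_mapq)
  structure(list(
    replicate_id = replicate_id, gene_id = model$gene_id,
    cds = region_coverage(src$value, model, "CDS", min_mapq, counts),
    utr3 = region_coverage(src$value, model, "UTR3", min_mapq, counts),
    gene_read_count = gene_read_count(src$value, model, min_mapq, counts),
    total_mapped_reads = total_mapped_reads), class = "CoverageTrack")
}
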