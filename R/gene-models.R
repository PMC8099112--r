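#' Construct a gene model with CDS and 3'UTR intervals
#'
#' A `GeneModel` holds the strand-aware CDS and 3'UTR interval sets of one
#' gene together with the CDS-3'UTR junction: the transcript position where
#' the coding sequence ends and the 3'UTR begins (the stop-codon boundary).
#' Intervals are normalised at construction: each set is reduced to disjoint
#' sorted ranges, and bases claimed by both sets are assigned to the CDS.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds,utr3 Coding and 3'UTR intervals: an `IRanges`, or a BED-style
#'   `data.frame` with 0-based `start` and exclusive `end` columns.
#' @param gene_name Display name; defaults to `gene_id`.
#'
#' @return An object of class `GeneModel`: a list with elements `gene_id`,
#'   `gene_name`, `chrom`, `strand`, `cds` and `utr3` (disjoint sorted
#'   `IRanges`), and `junction`, the BED-style (0-based boundary) genomic
#'   coordinate separating CDS from 3'UTR. On the plus strand the junction
#'   equals the genomic end of the last CDS base; on the minus strand it is
#'   the boundary immediately 5' (genomically left) of the first CDS base.
#' @export
gene_model <- function(gene_id, chrom, strand, cds, utr3, gene_name = gene_id) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  cds <- IRanges::reduce(as_region_iranges(cds))
  utr3 <- IRanges::reduce(as_region_iranges(utr3))
  utr3 <- IRanges::setdiff(utr3, cds)  # shared bases belong to the CDS
  if (length(cds) == 0L || sum(IRanges::width(cds)) < 1L)
    stop("gene ", gene_id, ": empty CDS")
  if (length(utr3) == 0L || sum(IRanges::width(utr3)) < 1L)
    stop("gene ", gene_id, ": empty 3'UTR")
  junction <- if (strand == "+") max(IRanges::end(cds)) else min(IRanges::start(cds)) - 1L
  structure(list(gene_id = gene_id, gene_name = gene_name, chrom = chrom,
                 strand = strand, cds = cds, utr3 = utr3,
                 junction = as.integer(junction)),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat(sprintf("GeneModel %s (%s) %s%s | CDS %d bp in %d interval(s), 3'UTR %d bp in %d interval(s), junction %d\n",
              x$gene_id, x$gene_name, x$chrom, x$strand,
              cds_length(x), length(x$cds), utr3_length(x), length(x$utr3),
              x$junction))
  invisible(x)
}

# ---- annotation loading -----------------------------------------------------

.detect_annotation_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("bed", "bed12")) return("bed")
  if (ext %in% c("gtf", "gff", "gff2", "gff3")) return("gff")
  stop("cannot infer annotation format from extension of ", path,
       " (expected .gtf/.gff/.gff3 or .bed)")
}

# 3' UTR of one transcript by exon-minus-CDS arithmetic
.derive_utr3 <- function(exons, cds, strand) {
  rest <- IRanges::setdiff(exons, cds)
  if (length(rest) == 0L) return(rest)
  if (strand == "+") {
    rest[IRanges::start(rest) > max(IRanges::end(cds))]
  } else {
    rest[IRanges::end(rest) < min(IRanges::start(cds))]
  }
}

#' Load per-gene CDS/3'UTR models from standard annotation
#'
#' Reads GTF/GFF3 (requires `gene_id` and `transcript_id` attributes) or
#' BED12 and returns one [gene_model()] per gene that has both a nonempty CDS
#' and a nonempty 3'UTR. 3'UTRs are taken from explicit `three_prime_utr`
#' features when present, otherwise derived as the exonic bases 3' of the
#' CDS. In BED12, the thick range defines the CDS span and block rows with a
#' shared `name` are treated as transcripts of one gene.
#'
#' @param path Annotation file (`.gtf`, `.gff`, `.gff3` or `.bed`).
#' @param transcript_policy How multi-transcript genes are collapsed:
#'   `"union"` (default) takes the union of CDS intervals and the union of
#'   3'UTR intervals across transcripts, assigning bases in both unions to
#'   the CDS; `"longest"` keeps the single transcript with the largest total
#'   exon length.
#' @param format Override the extension-based format guess (`"gff"` or `"bed"`).
#'
#' @return Named list of `GeneModel`s. Genes lacking a CDS or a 3'UTR (or
#'   with CDS on several strands/chromosomes) are skipped; the skipped gene
#'   ids and reasons are attached as attribute `"skipped"` and reported via
#'   a message.
#' @export
load_gene_models <- function(path, transcript_policy = c("union", "longest"),
                             format = NULL) {
  transcript_policy <- match.arg(transcript_policy)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  format <- if (is.null(format)) .detect_annotation_format(path) else format

  per_gene <- if (format == "bed") .gene_parts_bed12(path) else .gene_parts_gff(path)

  models <- list(); skipped <- list()
  for (gid in names(per_gene)) {
    g <- per_gene[[gid]]
    if (length(unique(g$strand)) != 1L || !all(g$strand %in% c("+", "-"))) {
      skipped[[gid]] <- "CDS on both strands"; next
    }
    if (length(unique(g$chrom)) != 1L) { skipped[[gid]] <- "multiple chromosomes"; next }
    tx <- g$transcripts
    tx <- tx[vapply(tx, function(t) length(t$cds) > 0L, logical(1))]
    if (length(tx) == 0L) { skipped[[gid]] <- "no CDS"; next }
    if (transcript_policy == "longest") {
      exlen <- vapply(tx, function(t) sum(IRanges::width(t$exons)), numeric(1))
      tx <- tx[which.max(exlen)]
    }
    cds_u <- IRanges::reduce(do.call(c, unname(lapply(tx, `[[`, "cds"))))
    utr_list <- lapply(tx, function(t) {
      if (length(t$utr3) > 0L) t$utr3 else .derive_utr3(t$exons, t$cds, g$strand[1])
    })
    utr_u <- IRanges::reduce(do.call(c, unname(utr_list)))
    utr_u <- IRanges::setdiff(utr_u, cds_u)
    if (length(utr_u) == 0L) { skipped[[gid]] <- "no 3'UTR"; next }
    models[[gid]] <- gene_model(gid, g$chrom[1], g$strand[1], cds_u, utr_u,
                                gene_name = g$gene_name)
  }
  if (length(skipped)) {
    message(length(skipped), " gene(s) skipped (no CDS, no 3'UTR, or ambiguous strand/chromosome)")
    attr(models, "skipped") <- data.frame(gene_id = names(skipped),
                                          reason = unlist(skipped),
                                          row.names = NULL)
  }
  models
}

.gene_parts_gff <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if (!all(c("gene_id", "transcript_id") %in% names(mc)))
    stop("annotation must carry gene_id and transcript_id attributes: ", path)
  type <- tolower(as.character(mc$type))
  keep <- type %in% c("cds", "exon", "three_prime_utr", "3utr", "utr3")
  gr <- gr[keep]; mc <- S4Vectors::mcols(gr); type <- type[keep]
  gname <- if ("gene_name" %in% names(mc)) as.character(mc$gene_name) else as.character(mc$gene_id)
  gid <- as.character(mc$gene_id); tid <- as.character(mc$transcript_id)
  out <- list()
  for (g in unique(gid)) {
    idx <- which(gid == g)
    txs <- list()
    for (t in unique(tid[idx])) {
      j <- idx[tid[idx] == t]
      rng <- IRanges::ranges(gr[j])
      txs[[t]] <- list(
        cds  = IRanges::reduce(rng[type[j] == "cds"]),
        exons = IRanges::reduce(rng[type[j] == "exon"]),
        utr3 = IRanges::reduce(rng[type[j] %in% c("three_prime_utr", "3utr", "utr3")]))
    }
    out[[g]] <- list(chrom = unique(as.character(GenomicRanges::seqnames(gr[idx]))),
                     strand = unique(as.character(GenomicRanges::strand(gr[idx]))),
                     gene_name = gname[idx][1],
                     transcripts = txs)
  }
  out
}

.gene_parts_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$name)) stop("BED12 rows must carry a name (gene id): ", path)
  blocks <- rtracklayer::blocks(gr)
  out <- list()
  for (i in seq_along(gr)) {
    gid <- gr$name[i]
    strand <- as.character(GenomicRanges::strand(gr[i]))
    exons <- IRanges::reduce(IRanges::ranges(blocks[[i]]))
    thick <- IRanges::ranges(gr$thick[i])
    cds <- if (IRanges::width(thick) > 1L || IRanges::start(thick) <= IRanges::end(thick))
      IRanges::intersect(exons, thick) else IRanges::IRanges()
    utr3 <- if (length(cds)) .derive_utr3(exons, cds, strand) else IRanges::IRanges()
    tx <- list(cds = cds, exons = exons, utr3 = utr3)
    if (is.null(out[[gid]])) {
      out[[gid]] <- list(chrom = as.character(GenomicRanges::seqnames(gr[i])),
                         strand = strand, gene_name = gid, transcripts = list(tx))
    } else {
      out[[gid]]$chrom <- unique(c(out[[gid]]$chrom, as.character(GenomicRanges::seqnames(gr[i]))))
      out[[gid]]$strand <- unique(c(out[[gid]]$strand, strand))
      out[[gid]]$transcripts <- c(out[[gid]]$transcripts, list(tx))
    }
  }
  out
}

# ---- junction flanks --------------------------------------------------------

#' Transcript-oriented bins flanking the CDS-3'UTR junction
#'
#' Returns `n_bins` bins of `bin_size` bp on each side of the junction, in
#' BED-style genomic coordinates, labelled by signed transcript offset:
#' offset -1 is the bin immediately 5' of the junction (CDS side), +1 the bin
#' immediately 3' (3'UTR side). Bins are clipped to the gene span and flagged
#' `partial` when clipping shortened them; bins falling entirely outside the
#' span are dropped.
#'
#' @param model A [gene_model()].
#' @param bin_size Bin width in bp (default 250).
#' @param n_bins Number of bins on each side (default 1).
#' @return `data.frame` with columns `offset`, `chrom`, `start`, `end`,
#'   `strand`, `partial`.
#' @export
junction_flank <- function(model, bin_size = 250L, n_bins = 1L) {
  stopifnot(bin_size > 0, n_bins >= 1)
  j <- model$junction
  span <- gene_span(model)
  rows <- list()
  for (k in seq_len(n_bins)) {
    for (side in c(-1L, 1L)) {
      # genomic direction of "5' of junction" depends on strand
      if ((model$strand == "+" && side < 0) || (model$strand == "-" && side > 0)) {
        s <- j - k * bin_size; e <- j - (k - 1L) * bin_size
      } else {
        s <- j + (k - 1L) * bin_size; e <- j + k * bin_size
      }
      cs <- max(s, span["start"]); ce <- min(e, span["end"])
      if (cs >= ce) next
      rows[[length(rows) + 1L]] <- data.frame(
        offset = side * k, chrom = model$chrom, start = cs, end = ce,
        strand = model$strand, partial = (cs != s || ce != e))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- writers ----------------------------------------------------------------

#' Write per-gene region BED6 (`gene|CDS`, `gene|UTR3`)
#' @param models List of `GeneModel`s.
#' @param path Output BED6 path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(models, path) {
  rows <- lapply(models, function(m) {
    rbind(
      cbind(iranges_to_bed(m$cds), name = paste0(m$gene_id, "|CDS")),
      cbind(iranges_to_bed(m$utr3), name = paste0(m$gene_id, "|UTR3")))
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  chrom <- rep(vapply(models, `[[`, "", "chrom"),
               vapply(models, function(m) length(m$cds) + length(m$utr3), 0L))
  strand <- rep(vapply(models, `[[`, "", "strand"),
                vapply(models, function(m) length(m$cds) + length(m$utr3), 0L))
  bed <- data.frame(chrom = chrom, start = df$start, end = df$end,
                    name = df$name, score = 0L, strand = strand)
  bed <- bed[order(bed$chrom, bed$start), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as BED12 (one row per gene)
#'
#' The thick range encodes the CDS genomic span; blocks are the sorted union
#' of CDS and 3'UTR intervals. Assumes (and warns otherwise) that no 3'UTR
#' interval falls genomically inside the CDS span, so the file round-trips
#' through [load_gene_models()].
#' @param models List of `GeneModel`s.
#' @param path Output BED12 path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(models, path) {
  lines <- vapply(models, function(m) {
    cds_span <- range(m$cds)
    if (any(IRanges::overlapsAny(m$utr3, cds_span)))
      warning("gene ", m$gene_id, ": 3'UTR interval inside CDS span; BED12 will not round-trip")
    blocks <- IRanges::reduce(c(m$cds, m$utr3))  # reduce returns sorted ranges
    s0 <- min(IRanges::start(blocks)) - 1L
    e <- max(IRanges::end(blocks))
    sizes <- paste0(paste(IRanges::width(blocks), collapse = ","), ",")
    starts <- paste0(paste(IRanges::start(blocks) - 1L - s0, collapse = ","), ",")
    paste(m$chrom, s0, e, m$gene_id, 0L, m$strand,
          min(IRanges::start(m$cds)) - 1L, max(IRanges::end(m$cds)),
          0L, length(blocks), sizes, starts, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
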