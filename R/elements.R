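# Alignment of genomic element tracks (CpG islands, TF clusters, miRNA
# sites, H3K27ac, DNase hypersensitive sites, ...) to called 3'UTR peaks
# and valleys, with a length-preserving permutation null.

#' Read an element BED6 with a category label
#'
#' The category is taken from a 7th column when present, otherwise from the
#' BED name field.
#' @param path BED path.
#' @return `GRanges` with a `category` metadata column.
#' @export
read_elements_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop("element BED needs at least 4 columns: ", path)
  gr <- GenomicRanges::GRanges(raw[[1]], bed_to_iranges(raw[[2]], raw[[3]]),
                               strand = if (ncol(raw) >= 6) raw[[6]] else "*")
  gr$category <- if (ncol(raw) >= 7) as.character(raw[[7]]) else as.character(raw[[4]])
  gr
}

# Peak/valley/elsewhere assignment of element midpoints within the gene span.
# Returns factor levels peak/valley/elsewhere/outside.
.assign_elements <- function(elements, peakset, model, mode = "midpoint") {
  span <- gene_span(model)
  proj <- function(iv) {
    if (is.null(iv) || nrow(iv) == 0L) return(GenomicRanges::GRanges())
    unlist(project_to_genomic(model, iv))
  }
  pk_g <- proj(peakset$peaks); vl_g <- proj(peakset$valleys)
  on_chrom <- as.character(GenomicRanges::seqnames(elements)) == model$chrom
  if (mode == "midpoint") {
    mid <- GenomicRanges::start(elements) +
      (GenomicRanges::width(elements) - 1L) %/% 2L
    probe <- GenomicRanges::GRanges(model$chrom, IRanges::IRanges(mid, mid))
    in_span <- on_chrom & mid > span["start"] & mid <= span["end"]
  } else {
    probe <- GenomicRanges::GRanges(model$chrom, IRanges::ranges(elements))
    in_span <- on_chrom &
      GenomicRanges::start(elements) <= span["end"] &
      GenomicRanges::end(elements) > span["start"]
  }
  in_peak <- IRanges::overlapsAny(probe, pk_g, ignore.strand = TRUE) & in_span
  in_valley <- IRanges::overlapsAny(probe, vl_g, ignore.strand = TRUE) &
    in_span & !in_peak
  out <- ifelse(!in_span, "outside",
         ifelse(in_peak, "peak", ifelse(in_valley, "valley", "elsewhere")))
  factor(out, levels = c("peak", "valley", "elsewhere", "outside"))
}

#' Overlap of element tracks with 3'UTR peaks and valleys
#'
#' Assigns each element (by midpoint, default, or by any overlap) to the
#' called peaks, the called valleys, or elsewhere within the gene span;
#' elements outside the span are excluded and reported separately.
#'
#' @param elements `GRanges` with a `category` metadata column (see
#'   [read_elements_bed()]).
#' @param peakset A [peak_set()].
#' @param model The matching [gene_model()].
#' @param mode `"midpoint"` (default; avoids double-assignment of long
#'   elements spanning a peak edge) or `"any"`.
#' @return `data.frame`, one row per category: counts in peaks, valleys and
#'   elsewhere, `n_outside_span`, and `peak_fraction` among in-span elements.
#' @export
element_overlap <- function(elements, peakset, model,
                            mode = c("midpoint", "any")) {
  mode <- match.arg(mode)
  if (is.null(elements$category)) stop("elements need a 'category' metadata column")
  asg <- .assign_elements(elements, peakset, model, mode)
  cats <- unique(as.character(elements$category))
  rows <- lapply(cats, function(cat) {
    a <- asg[elements$category == cat]
    n_in <- sum(a != "outside")
    data.frame(category = cat,
               n_in_peaks = sum(a == "peak"),
               n_in_valleys = sum(a == "valley"),
               n_elsewhere = sum(a == "elsewhere"),
               n_outside_span = sum(a == "outside"),
               peak_fraction = if (n_in > 0) sum(a == "peak") / n_in else NA_real_)
  })
  do.call(rbind, rows)
}

#' Permutation test for element concentration in peaks
#'
#' Null model: each element is placed uniformly at random (length-preserving)
#' within the gene span, independently, and assigned by midpoint.
#' `empirical_p = (1 + #\{perm peak_fraction >= observed\}) / (1 + n_perm)`.
#'
#' @param elements `GRanges` of one category.
#' @param peakset A [peak_set()].
#' @param model The matching [gene_model()].
#' @param n_perm Number of permutations (default 1000; must be >= 1).
#' @param seed Optional integer; fixes the permutation stream without
#'   touching the caller's RNG state.
#' @return List with `observed_peak_fraction`, `empirical_p`, `n_perm`,
#'   `n_elements`.
#' @export
element_permutation_test <- function(elements, peakset, model,
                                     n_perm = 1000L, seed = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (length(elements) < 1L) stop("need at least one element")
  span <- gene_span(model)
  span_len <- span["end"] - span["start"]

  pk <- peakset$peaks
  pk_g <- if (!is.null(pk) && nrow(pk) > 0L) unlist(project_to_genomic(model, pk))
          else GenomicRanges::GRanges()
  # logical membership over the span, indexed by BED offset - span_start
  in_peak <- logical(span_len)
  if (length(pk_g)) {
    for (i in seq_along(pk_g)) {
      s <- max(GenomicRanges::start(pk_g)[i] - 1L, span["start"]) - span["start"]
      e <- min(GenomicRanges::end(pk_g)[i], span["end"]) - span["start"]
      if (e > s) in_peak[(s + 1L):e] <- TRUE
    }
  }
  if (all(in_peak)) {
    warning("peaks cover the entire gene span; permutation test degenerate")
    return(list(observed_peak_fraction = 1, empirical_p = 1,
                n_perm = n_perm, n_elements = length(elements)))
  }

  midpoint_in_peak <- function(mid0) {
    idx <- mid0 - span["start"]         # BED offset of midpoint base
    ok <- idx >= 0 & idx < span_len
    res <- logical(length(mid0)); res[ok] <- in_peak[idx[ok] + 1L]
    res
  }
  obs_mid <- GenomicRanges::start(elements) +
    (GenomicRanges::width(elements) - 1L) %/% 2L - 1L  # BED offset
  observed <- mean(midpoint_in_peak(obs_mid))

  lens <- GenomicRanges::width(elements)
  run <- function() {
    k <- length(lens)
    max_start <- pmax(span["end"] - lens, span["start"])
    fr <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      starts <- span["start"] + floor(stats::runif(k) * (max_start - span["start"] + 1L))
      fr[p] <- mean(midpoint_in_peak(starts + (lens - 1L) %/% 2L))
    }
    fr
  }
  fr <- if (is.null(seed)) run() else {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    run()
  }
  p <- (1 + sum(fr >= observed)) / (1 + n_perm)
  list(observed_peak_fraction = unname(observed), empirical_p = unname(p),
       n_perm = n_perm, n_elements = length(elements))
}
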