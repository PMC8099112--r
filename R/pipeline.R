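#' Validate a pipeline run configuration
#'
#' @param annotation Gene annotation path (GTF/GFF3/BED12).
#' @param coverage Character vector of per-replicate coverage inputs (BAM or
#'   bedGraph), named by replicate id.
#' @param library_sizes Numeric total-mapped-read counts, one per replicate
#'   (same order as `coverage`).
#' @param counts Per-replicate read-count TSVs (`gene_id`, `region`,
#'   `read_count`) — required for bedGraph inputs, ignored for BAM.
#' @param ests Optional EST BED6 path.
#' @param elements Optional element BED path (category in the name field or
#'   a 7th column).
#' @param class_params A [classification_params()].
#' @param peak_params A [peak_params()].
#' @param ratio_basis `"expression"` or `"mean_depth"` (see
#'   [gene_ratio_table()]).
#' @param concordance_metric `"jaccard"` or `"overlap_smaller"`.
#' @param transcript_policy Passed to [load_gene_models()].
#' @param min_mapq BAM MAPQ filter.
#' @param n_perm Permutations for the element test.
#' @param seed Seed fixing any randomised step.
#' @return A validated `RunConfig` list.
#' @export
run_config <- function(annotation, coverage, library_sizes, counts = NULL,
                       ests = NULL, elements = NULL,
                       class_params = classification_params(),
                       peak_params = isoutr::peak_params(),
                       ratio_basis = c("expression", "mean_depth"),
                       concordance_metric = c("jaccard", "overlap_smaller"),
                       transcript_policy = "union",
                       min_mapq = 20L, n_perm = 1000L, seed = 1L) {
  ratio_basis <- match.arg(ratio_basis)
  concordance_metric <- match.arg(concordance_metric)
  if (!inherits(class_params, "ClassificationParams"))
    stop("class_params must come from classification_params()")
  if (!inherits(peak_params, "PeakParams"))
    stop("peak_params must come from peak_params()")
  for (p in c(annotation, coverage, counts, ests, elements))
    if (!is.null(p) && !is.na(p) && !file.exists(p)) stop("input not found: ", p)
  if (length(library_sizes) != length(coverage))
    stop("library_sizes must match coverage inputs one-to-one")
  if (!is.null(counts) && length(counts) != length(coverage))
    stop("counts must match coverage inputs one-to-one")
  if (is.null(names(coverage)))
    names(coverage) <- sprintf("rep%d", seq_along(coverage))
  library_sizes <- stats::setNames(library_sizes, names(coverage))
  structure(list(annotation = annotation, coverage = coverage,
                 library_sizes = library_sizes, counts = counts,
                 ests = ests, elements = elements,
                 class_params = class_params, peak_params = peak_params,
                 ratio_basis = ratio_basis,
                 concordance_metric = concordance_metric,
                 transcript_policy = transcript_policy,
                 min_mapq = as.integer(min_mapq), n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full isolated-3'UTR analysis pipeline
#'
#' Stages, in dependency order: gene models -> per-replicate region
#' quantification -> ratio classification (per-replicate, pooled, replicate
#' concordance, ranked class lists) -> consensus 3'UTR peaks/valleys and
#' pattern types -> EST summaries -> element overlap with permutation test.
#' The EST and element stages run only when their inputs are configured.
#' All outputs are TSV/BED files under `out_dir` plus a JSON manifest
#' recording parameters and input checksums; a rerun with an identical
#' configuration reproduces identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list of in-memory stage results (`models`, `quant`,
#'   `ratios`, `pooled`, `concordance`, `peaksets`, `patterns`,
#'   `est_summaries`, `element_overlaps`, `manifest_path`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  notes <- character(0)
  reps <- names(config$coverage)

  models <- .stage("models", load_gene_models(config$annotation,
                                              config$transcript_policy))
  if (length(models) == 0L) stop("pipeline stage 'models': no usable genes")
  write_region_bed(models, file.path(out_dir, "gene_regions.bed"))

  # --- quantification ---------------------------------------------------
  quant <- list(); tracks <- list()
  for (i in seq_along(config$coverage)) {
    r <- reps[i]
    cnt <- if (!is.null(config$counts))
      utils::read.table(config$counts[i], header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE) else NULL
    q <- .stage(paste0("quantify:", r),
                quantify_regions(models, config$coverage[i],
                                 config$library_sizes[i], replicate_id = r,
                                 min_mapq = config$min_mapq, counts = cnt,
                                 keep_depth = TRUE))
    tracks[[r]] <- attr(q, "tracks")
    attr(q, "tracks") <- NULL
    quant[[r]] <- q
  }
  write_expression_tsv(do.call(rbind, quant),
                       file.path(out_dir, "expression.tsv"))

  # --- ratios and classification ---------------------------------------
  ratios <- .stage("ratios", lapply(quant, gene_ratio_table,
                                    params = config$class_params,
                                    ratio_basis = config$ratio_basis))
  pooled <- .stage("ratios", .pooled_ratio_table(tracks, config))
  out_ratios <- cbind(replicate_id = rep(c(reps, "pooled"),
                                         each = nrow(pooled)),
                      do.call(rbind, c(ratios, list(pooled))))
  utils::write.table(out_ratios, file.path(out_dir, "gene_ratios.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_class_lists(pooled, out_dir, config$class_params)

  conc <- NULL
  if (length(reps) > 1L) {
    pairs <- utils::combn(reps, 2L)
    conc <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      hi_a <- ratios[[a]]$gene_id[ratios[[a]]$klass == "HI_UTR"]
      hi_b <- ratios[[b]]$gene_id[ratios[[b]]$klass == "HI_UTR"]
      cbind(replicate_a = a, replicate_b = b,
            replicate_concordance(hi_a, hi_b, config$concordance_metric))
    }))
    utils::write.table(conc, file.path(out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- peaks, valleys, patterns -----------------------------------------
  peaksets <- list(); patt_rows <- list()
  for (gid in names(models)) {
    utr_fpkm <- vapply(reps, function(r)
      per_base_fpkm(tracks[[r]][[gid]]$utr3$depth, config$library_sizes[r]),
      numeric(length(tracks[[reps[1]]][[gid]]$utr3$depth)))
    cds_fpkm <- vapply(reps, function(r)
      per_base_fpkm(tracks[[r]][[gid]]$cds$depth, config$library_sizes[r]),
      numeric(length(tracks[[reps[1]]][[gid]]$cds$depth)))
    pat <- .stage(paste0("peaks:", gid),
                  classify_pattern(cds_fpkm, utr_fpkm, config$peak_params))
    peaksets[[gid]] <- peak_set(gid, pat)
    patt_rows[[gid]] <- data.frame(gene_id = gid,
                                   n_peaks = nrow(pat$utr_peaks),
                                   n_valleys = nrow(pat$utr_valleys),
                                   pattern_type = pat$pattern_type,
                                   rule_trace = pat$rule_trace)
  }
  patterns <- do.call(rbind, patt_rows)
  utils::write.table(patterns, file.path(out_dir, "patterns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_peaks_bed(models, peaksets, "peaks", file.path(out_dir, "peaks.bed"))
  write_peaks_bed(models, peaksets, "valleys", file.path(out_dir, "valleys.bed"))

  # --- ESTs --------------------------------------------------------------
  est_summaries <- NULL
  if (!is.null(config$ests) && !is.na(config$ests)) {
    est_gr <- .stage("ests", rtracklayer::import(config$ests, format = "bed"))
    sums <- list(); bins <- list()
    for (gid in names(models)) {
      m <- models[[gid]]
      span <- gene_span(m)
      sel <- est_gr[as.character(GenomicRanges::seqnames(est_gr)) == m$chrom &
                    GenomicRanges::start(est_gr) <= span["end"] &
                    GenomicRanges::end(est_gr) > span["start"]]
      if (length(sel) == 0L) next
      s <- .stage(paste0("ests:", gid),
                  summarize_ests(sel, m, peaksets[[gid]]))
      sums[[gid]] <- s$summary
      bins[[gid]] <- cbind(gene_id = gid, s$bins)
    }
    est_summaries <- do.call(rbind, sums)
    utils::write.table(est_summaries, file.path(out_dir, "est_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(do.call(rbind, bins),
                       file.path(out_dir, "junction_bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else notes <- c(notes, "EST stage skipped: no EST BED configured")

  # --- elements ----------------------------------------------------------
  element_overlaps <- NULL
  if (!is.null(config$elements) && !is.na(config$elements)) {
    el_gr <- .stage("elements", read_elements_bed(config$elements))
    rows <- list()
    for (gid in names(models)) {
      m <- models[[gid]]
      span <- gene_span(m)
      sel <- el_gr[as.character(GenomicRanges::seqnames(el_gr)) == m$chrom &
                   GenomicRanges::start(el_gr) <= span["end"] &
                   GenomicRanges::end(el_gr) > span["start"]]
      if (length(sel) == 0L) next
      ov <- .stage(paste0("elements:", gid),
                   element_overlap(sel, peaksets[[gid]], m))
      ov$empirical_p <- vapply(ov$category, function(cat) {
        if (nrow(peaksets[[gid]]$peaks) == 0L) return(NA_real_)
        element_permutation_test(sel[sel$category == cat], peaksets[[gid]], m,
                                 n_perm = config$n_perm,
                                 seed = config$seed)$empirical_p
      }, numeric(1))
      rows[[gid]] <- cbind(gene_id = gid, ov)
    }
    element_overlaps <- do.call(rbind, rows)
    utils::write.table(element_overlaps,
                       file.path(out_dir, "element_overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else notes <- c(notes, "element stage skipped: no element BED configured")

  # --- manifest ----------------------------------------------------------
  inputs <- c(annotation = config$annotation, config$coverage,
              if (!is.null(config$counts)) stats::setNames(config$counts, paste0("counts_", reps)),
              if (!is.null(config$ests)) c(ests = config$ests),
              if (!is.null(config$elements)) c(elements = config$elements))
  manifest <- list(
    tool = "isoutr", version = as.character(utils::packageVersion("isoutr")),
    n_replicates = length(reps), replicates = reps,
    parameters = list(
      class_params = unclass(config$class_params),
      peak_params = unclass(config$peak_params),
      ratio_basis = config$ratio_basis,
      concordance_metric = config$concordance_metric,
      transcript_policy = config$transcript_policy,
      min_mapq = config$min_mapq, n_perm = config$n_perm, seed = config$seed),
    inputs = as.list(inputs),
    input_md5 = as.list(tools::md5sum(unname(inputs))),
    outputs = list.files(out_dir),
    notes = notes)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(models = models, quant = quant, ratios = ratios,
                 pooled = pooled, concordance = conc, peaksets = peaksets,
                 patterns = patterns, est_summaries = est_summaries,
                 element_overlaps = element_overlaps,
                 manifest_path = manifest_path))
}

# Pooled record: summed counts, effective length from summed depth,
# summed library sizes.
.pooled_ratio_table <- function(tracks, config) {
  reps <- names(tracks)
  gids <- names(tracks[[1]])
  lib <- sum(config$library_sizes)
  rows <- list()
  for (gid in gids) {
    for (region in c("CDS", "UTR3")) {
      key <- if (region == "CDS") "cds" else "utr3"
      depth <- Reduce(`+`, lapply(reps, function(r) tracks[[r]][[gid]][[key]]$depth))
      rc <- sum(vapply(reps, function(r) tracks[[r]][[gid]][[key]]$read_count, numeric(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_id = "pooled", gene_id = gid, region = region,
        read_count = rc, region_length_bp = length(depth),
        effective_length_bp = effective_length(depth),
        sum_depth = sum(depth),
        expression = normalized_expression(rc, effective_length(depth), lib),
        gene_read_count = sum(vapply(reps, function(r)
          tracks[[r]][[gid]]$gene_read_count, numeric(1))))
    }
  }
  gene_ratio_table(do.call(rbind, rows), config$class_params,
                   config$ratio_basis)
}
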