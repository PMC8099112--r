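#' Fractional 3'UTR-to-CDS ratio
#'
#' `utr / (utr + cds)`: 0 means all expression in the CDS, 1 all in the
#' 3'UTR. Undefined (returned as `NA` with a warning) when both inputs are
#' zero; such records are excluded from classification.
#'
#' @param utr_expression,cds_expression Non-negative expression values
#'   (vectorised).
#' @return Ratio in `[0, 1]`, or `NA` where both inputs are 0.
#' @export
fractional_ratio <- function(utr_expression, cds_expression) {
  stopifnot(all(utr_expression >= 0), all(cds_expression >= 0))
  tot <- utr_expression + cds_expression
  out <- ifelse(tot > 0, utr_expression / tot, NA_real_)
  if (anyNA(out)) warning("undefined ratio for ", sum(is.na(out)),
                          " record(s) with zero expression in both regions")
  as.numeric(out)
}

#' Hi/Lo classification thresholds
#'
#' Defaults follow the published rule: Hi 3'UTR means ratio strictly above
#' 0.6, Lo 3'UTR (Hi CDS) strictly below 0.4, on the 0 (high CDS) to 1
#' (high 3'UTR) scale, with genes below 5 total mapped reads set aside as
#' not expressed.
#'
#' @param hi_threshold,lo_threshold Strict classification bounds,
#'   `0 <= lo < hi <= 1`.
#' @param min_reads Expressed-gene read threshold.
#' @return A `ClassificationParams` list.
#' @export
classification_params <- function(hi_threshold = 0.6, lo_threshold = 0.4,
                                  min_reads = 5L) {
  if (!(lo_threshold >= 0 && lo_threshold < hi_threshold && hi_threshold <= 1))
    stop("need 0 <= lo_threshold < hi_threshold <= 1")
  if (min_reads < 0) stop("min_reads must be >= 0")
  structure(list(hi_threshold = hi_threshold, lo_threshold = lo_threshold,
                 min_reads = as.integer(min_reads)),
            class = "ClassificationParams")
}

.klass_levels <- c("HI_UTR", "HI_CDS", "INTERMEDIATE", "NOT_EXPRESSED")

#' Classify genes by fractional ratio
#'
#' Strict inequalities at both thresholds: a ratio exactly at a threshold is
#' `INTERMEDIATE`. Non-expressed genes are `NOT_EXPRESSED` regardless of
#' ratio.
#'
#' @param ratio Fractional ratios (may contain `NA`).
#' @param expressed Logical expressed flags.
#' @param params A [classification_params()].
#' @return Factor with levels `HI_UTR`, `HI_CDS`, `INTERMEDIATE`,
#'   `NOT_EXPRESSED`.
#' @export
classify_gene <- function(ratio, expressed, params = classification_params()) {
  stopifnot(length(ratio) == length(expressed))
  out <- rep(NA_character_, length(ratio))
  out[!expressed] <- "NOT_EXPRESSED"
  def <- expressed & !is.na(ratio)
  out[def & ratio > params$hi_threshold] <- "HI_UTR"
  out[def & ratio < params$lo_threshold] <- "HI_CDS"
  out[def & is.na(out)] <- "INTERMEDIATE"
  factor(out, levels = .klass_levels)
}

#' Per-gene ratio records from a quantification table
#'
#' @param quant Long table from [quantify_regions()] (one replicate, or a
#'   pooled table in the same shape).
#' @param params A [classification_params()].
#' @param ratio_basis `"expression"` computes the ratio on normalized
#'   expression (library size cancels; effective-length normalization makes
#'   regions of different length comparable). `"mean_depth"` uses mean
#'   per-base depth over the region instead.
#' @return `data.frame`: `gene_id`, `utr_expression`, `cds_expression`,
#'   `ratio`, `expressed`, `klass`.
#' @export
gene_ratio_table <- function(quant, params = classification_params(),
                             ratio_basis = c("expression", "mean_depth")) {
  ratio_basis <- match.arg(ratio_basis)
  val <- if (ratio_basis == "expression") quant$expression
         else quant$sum_depth / quant$region_length_bp
  cds <- quant$region == "CDS"
  utr <- quant$region == "UTR3"
  ids <- unique(quant$gene_id)
  ui <- match(ids, quant$gene_id[utr]); ci <- match(ids, quant$gene_id[cds])
  utr_e <- val[utr][ui]; cds_e <- val[cds][ci]
  expressed <- quant$gene_read_count[utr][ui] >= params$min_reads
  ratio <- suppressWarnings(fractional_ratio(utr_e, cds_e))
  data.frame(gene_id = ids, utr_expression = utr_e, cds_expression = cds_e,
             ratio = ratio, expressed = expressed,
             klass = classify_gene(ratio, expressed, params))
}

#' Replicate concordance of Hi-3'UTR gene sets
#'
#' Percent identity of two gene sets. The default metric is Jaccard x 100
#' (`100 * |A  intersect B| / |A union B|`); `"overlap_smaller"` divides by the
#' smaller set instead.
#'
#' @param hi_set_a,hi_set_b Character vectors of gene ids.
#' @param metric `"jaccard"` (default) or `"overlap_smaller"`.
#' @return One-row `data.frame`: `set_a_size`, `set_b_size`,
#'   `intersection_size`, `union_size`, `percent_identity` (`NA` with a
#'   warning when both sets are empty).
#' @export
replicate_concordance <- function(hi_set_a, hi_set_b,
                                  metric = c("jaccard", "overlap_smaller")) {
  metric <- match.arg(metric)
  a <- unique(hi_set_a); b <- unique(hi_set_b)
  ints <- length(intersect(a, b)); uni <- length(union(a, b))
  pid <- if (uni == 0L) {
    warning("concordance undefined: both sets empty"); NA_real_
  } else if (metric == "jaccard") {
    100 * ints / uni
  } else {
    100 * ints / min(length(a), length(b))
  }
  data.frame(set_a_size = length(a), set_b_size = length(b),
             intersection_size = ints, union_size = uni,
             percent_identity = pid, metric = metric)
}

#' Export ranked Hi-3'UTR / Hi-CDS gene lists
#'
#' Writes two TSVs ready for submission to an enrichment service: `HI_UTR`
#' genes sorted by descending ratio and `HI_CDS` genes by ascending ratio
#' (ties broken by gene id). Also reports each class's share of expressed
#' genes.
#'
#' @param records Output of [gene_ratio_table()].
#' @param dir Output directory.
#' @param params The [classification_params()] used (recorded for shares).
#' @return Invisibly, a list with `hi_utr_path`, `hi_cds_path`, `n_expressed`
#'   and per-class `share` (fraction of expressed genes).
#' @export
export_class_lists <- function(records, dir, params = classification_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_exp <- sum(records$expressed, na.rm = TRUE)
  write_one <- function(klass, decreasing, path) {
    sel <- records[!is.na(records$klass) & records$klass == klass, , drop = FALSE]
    ord <- order(if (decreasing) -sel$ratio else sel$ratio, sel$gene_id)
    sel <- sel[ord, c("gene_id", "ratio", "utr_expression", "cds_expression")]
    utils::write.table(sel, path, sep = "\t", quote = FALSE, row.names = FALSE)
    nrow(sel)
  }
  hi_utr_path <- file.path(dir, "hi_utr_genes.tsv")
  hi_cds_path <- file.path(dir, "hi_cds_genes.tsv")
  n_hi <- write_one("HI_UTR", TRUE, hi_utr_path)
  n_lo <- write_one("HI_CDS", FALSE, hi_cds_path)
  invisible(list(hi_utr_path = hi_utr_path, hi_cds_path = hi_cds_path,
                 n_expressed = n_exp,
                 share = c(HI_UTR = if (n_exp > 0) n_hi / n_exp else NA_real_,
                           HI_CDS = if (n_exp > 0) n_lo / n_exp else NA_real_)))
}
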