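# Synthetic-data generator with ground truth.
#
# Genes are simulated as single-exon transcripts laid out on one synthetic
# chromosome. Each design fixes the CDS/3'UTR lengths, the true fractional
# 3'UTR share of expression, and a peak blueprint (offsets from the
# junction, lengths, design FPKM) over a valley floor. Designed FPKM is
# converted to expected per-base depth through the inverse of the per-base
# FPKM formula (depth = fpkm * library_size / 1e9) and noise is applied per
# base (Poisson) or per 50-bp tile (negative binomial). The CDS baseline
# FPKM is solved from the designed ratio so that the mean-coverage ratio of
# the noise-free profiles equals the designed value.

#' Design one synthetic gene
#'
#' @param gene_id Unique gene id.
#' @param cds_length_bp,utr3_length_bp Region lengths (bp).
#' @param designed_ratio True 3'UTR share of expression, in (0, 1).
#' @param strand `"+"` or `"-"`.
#' @param peak_blueprints `data.frame(offset_bp, length_bp, design_fpkm)`;
#'   offsets are transcript positions relative to the junction (negative =
#'   extends into the CDS, for junction-spanning architectures). May be
#'   `NULL` for a flat 3'UTR.
#' @param valley_fpkm FPKM floor outside designed peaks (default 20).
#' @param pattern_type_truth Designed pattern label (`"TYPE_I"`, `"TYPE_II"`,
#'   `"TYPE_III"`, `"UNCLASSIFIED"`).
#' @return A `GeneDesign` list; the CDS baseline FPKM implied by
#'   `designed_ratio` is precomputed as `cds_base_fpkm`.
#' @export
gene_design <- function(gene_id, cds_length_bp, utr3_length_bp, designed_ratio,
                        strand = "+", peak_blueprints = NULL, valley_fpkm = 20,
                        pattern_type_truth = "UNCLASSIFIED") {
  stopifnot(cds_length_bp >= 1, utr3_length_bp >= 1,
            designed_ratio > 0, designed_ratio < 1, valley_fpkm >= 0)
  Lc <- as.integer(cds_length_bp); Lu <- as.integer(utr3_length_bp)
  bp <- peak_blueprints
  if (!is.null(bp) && nrow(bp) > 0L) {
    stopifnot(all(c("offset_bp", "length_bp", "design_fpkm") %in% names(bp)))
    bp <- bp[order(bp$offset_bp), , drop = FALSE]
    if (any(bp$design_fpkm <= 0)) stop("design_fpkm must be > 0")
    if (any(bp$offset_bp < -Lc) || any(bp$offset_bp + bp$length_bp > Lu))
      stop("peak blueprint outside the gene for ", gene_id)
    if (nrow(bp) > 1L &&
        any(bp$offset_bp[-1] < (bp$offset_bp + bp$length_bp)[-nrow(bp)]))
      stop("peak blueprints must be disjoint for ", gene_id)
  } else bp <- NULL

  # noise-free 3'UTR profile mean, and the CDS baseline solving the ratio
  utr_prof <- rep(valley_fpkm, Lu)
  spike_sum <- 0; spike_n <- 0L
  if (!is.null(bp)) for (i in seq_len(nrow(bp))) {
    s <- bp$offset_bp[i]; e <- s + bp$length_bp[i]
    us <- max(s, 0L); ue <- min(e, Lu)
    if (ue > us) utr_prof[(us + 1L):ue] <- bp$design_fpkm[i]
    if (s < 0L) {                       # CDS-side part of a junction peak
      n <- min(-s, Lc)
      spike_sum <- spike_sum + n * bp$design_fpkm[i]
      spike_n <- spike_n + n
    }
  }
  u_mean <- mean(utr_prof)
  target_cds_mean <- u_mean * (1 - designed_ratio) / designed_ratio
  cds_base <- (target_cds_mean * Lc - spike_sum) / (Lc - spike_n)
  if (cds_base < 0)
    stop("designed_ratio incompatible with junction-spanning blueprint for ", gene_id)

  structure(list(gene_id = gene_id, cds_length_bp = Lc, utr3_length_bp = Lu,
                 strand = strand, designed_ratio = designed_ratio,
                 peak_blueprints = bp, valley_fpkm = valley_fpkm,
                 cds_base_fpkm = cds_base,
                 pattern_type_truth = pattern_type_truth,
                 chrom = NA_character_, tx_start = NA_integer_),
            class = "GeneDesign")
}

#' Noise-free expected FPKM profiles of a design
#' @param design A [gene_design()].
#' @return List with `cds` and `utr` per-base FPKM vectors
#'   (transcript-oriented).
#' @export
expected_fpkm_profile <- function(design) {
  Lc <- design$cds_length_bp; Lu <- design$utr3_length_bp
  cds <- rep(design$cds_base_fpkm, Lc)
  utr <- rep(design$valley_fpkm, Lu)
  bp <- design$peak_blueprints
  if (!is.null(bp)) for (i in seq_len(nrow(bp))) {
    s <- bp$offset_bp[i]; e <- s + bp$length_bp[i]
    us <- max(s, 0L); ue <- min(e, Lu)
    if (ue > us) utr[(us + 1L):ue] <- bp$design_fpkm[i]
    if (s < 0L) cds[(Lc + max(s, -Lc) + 1L):Lc] <- bp$design_fpkm[i]
  }
  list(cds = cds, utr = utr)
}

# Designed 3'UTR peak intervals, clipped to the UTR (spliced BED offsets)
designed_utr_peaks <- function(design) {
  bp <- design$peak_blueprints
  if (is.null(bp)) return(data.frame(start = integer(0), end = integer(0)))
  s <- pmax(bp$offset_bp, 0L); e <- pmin(bp$offset_bp + bp$length_bp, design$utr3_length_bp)
  data.frame(start = s[e > s], end = e[e > s])
}

#' Simulation scenario configuration
#'
#' @param n_genes Genes drawn from the default design set (default 30, the
#'   full set).
#' @param n_replicates Replicate libraries (default 4).
#' @param library_size Total mapped reads per replicate; recycled to
#'   `n_replicates`. The default mimics 100M-read libraries with moderate
#'   size differences.
#' @param read_length Read length used to convert depth to read counts.
#' @param noise `"poisson"` (per-base), `"nb"` (negative binomial via a
#'   Gamma multiplier per 50-bp tile) or `"none"`.
#' @param nb_dispersion Gamma dispersion for `"nb"` noise.
#' @param est_mixture Class probabilities `c(utr_only, cds_only, mixed)`;
#'   must sum to 1.
#' @param n_ests ESTs per gene (default 200).
#' @param elements_per_category Named counts of elements per gene for genes
#'   with designed peaks.
#' @param seed Integer seed fixing all outputs.
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 30L, n_replicates = 4L,
                              library_size = round(1e8 * c(0.85, 1, 1.1, 1.2)),
                              read_length = 100L,
                              noise = c("poisson", "nb", "none"),
                              nb_dispersion = 0.15,
                              est_mixture = c(utr_only = 0.85, cds_only = 0.05,
                                              mixed = 0.10),
                              n_ests = 200L,
                              elements_per_category = c(miRNA_site = 3L,
                                                        TF_cluster = 2L,
                                                        CpG_island = 1L,
                                                        H3K27ac = 1L,
                                                        DNase = 1L),
                              seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  stopifnot(n_replicates >= 1, read_length >= 1, all(library_size > 0))
  if (abs(sum(est_mixture) - 1) > 1e-9) stop("est_mixture must sum to 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 library_size = rep_len(library_size, n_replicates),
                 read_length = as.integer(read_length),
                 noise = match.arg(noise), nb_dispersion = nb_dispersion,
                 est_mixture = est_mixture, n_ests = as.integer(n_ests),
                 elements_per_category = elements_per_category,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

.bp <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(offset_bp = m[, 1], length_bp = m[, 2], design_fpkm = m[, 3])
}

#' The default 30-gene design set
#'
#' Covers the three peak architectures plus flat-3'UTR genes, with designed
#' ratios spanning 0.05-0.95, on both strands: eight multi-peak genes
#' (`TYPE_I`), five short-3'UTR genes with a junction-contiguous peak
#' (`TYPE_II`), five long-3'UTR genes with a short leading CDS stretch
#' (`TYPE_III`), and twelve flat genes (`UNCLASSIFIED`) carrying the low and
#' intermediate ratios.
#' @return List of [gene_design()]s.
#' @export
default_gene_designs <- function() {
  d <- list(
    # TYPE_I: >=2 discrete internal 3'UTR peaks with valleys between
    gene_design("SG01", 1200, 3000, 0.70, "+", .bp(300, 500, 400, 1800, 500, 350), 20, "TYPE_I"),
    gene_design("SG02",  900, 2700, 0.75, "-", .bp(250, 400, 450, 1500, 600, 300), 20, "TYPE_I"),
    gene_design("SG03", 1500, 3600, 0.80, "+", .bp(300, 500, 400, 1400, 400, 500, 2600, 600, 350), 20, "TYPE_I"),
    gene_design("SG04", 1000, 2400, 0.85, "+", .bp(200, 450, 400, 1300, 500, 400), 20, "TYPE_I"),
    gene_design("SG05",  800, 3000, 0.90, "-", .bp(400, 600, 300, 1800, 700, 450), 20, "TYPE_I"),
    gene_design("SG06", 1100, 2600, 0.95, "+", .bp(250, 400, 500, 1500, 450, 350), 20, "TYPE_I"),
    gene_design("SG07", 1300, 3200, 0.72, "+", .bp(300, 600, 350, 1900, 500, 400), 20, "TYPE_I"),
    gene_design("SG08",  950, 2800, 0.88, "-", .bp(350, 500, 450, 1600, 550, 300), 20, "TYPE_I"),
    # TYPE_II: one junction-contiguous peak into a short 3'UTR
    gene_design("SG09",  900,  700, 0.82, "+", .bp(-40, 640, 400), 20, "TYPE_II"),
    gene_design("SG10", 1200,  800, 0.86, "-", .bp(-30, 700, 350), 20, "TYPE_II"),
    gene_design("SG11", 1000,  600, 0.80, "+", .bp(-50, 570, 450), 20, "TYPE_II"),
    gene_design("SG12",  800,  900, 0.90, "+", .bp(-20, 760, 400), 20, "TYPE_II"),
    gene_design("SG13", 1100,  750, 0.84, "-", .bp(-40, 680, 380), 20, "TYPE_II"),
    # TYPE_III: long 3'UTR, short leading CDS stretch at the junction
    gene_design("SG14",  800, 2400, 0.75, "+", .bp(-80, 880, 400, 1600, 500, 350), 20, "TYPE_III"),
    gene_design("SG15", 1000, 3000, 0.80, "+", .bp(-100, 900, 450, 1800, 600, 300), 20, "TYPE_III"),
    gene_design("SG16",  600, 2200, 0.70, "+", .bp(-60, 700, 400), 20, "TYPE_III"),
    gene_design("SG17", 1200, 2600, 0.78, "-", .bp(-120, 800, 380, 1500, 500, 400), 20, "TYPE_III"),
    gene_design("SG18",  900, 2000, 0.72, "+", .bp(-90, 690, 420), 20, "TYPE_III"),
    # flat 3'UTRs: low and intermediate designed ratios
    gene_design("SG19", 1000, 2000, 0.05, "+", NULL, 30, "UNCLASSIFIED"),
    gene_design("SG20",  900, 2200, 0.10, "-", NULL, 30, "UNCLASSIFIED"),
    gene_design("SG21", 1200, 1800, 0.15, "+", NULL, 30, "UNCLASSIFIED"),
    gene_design("SG22",  800, 2400, 0.20, "+", NULL, 30, "UNCLASSIFIED"),
    gene_design("SG23", 1100, 2000, 0.25, "-", NULL, 30, "UNCLASSIFIED"),
    gene_design("SG24", 1000, 2600, 0.30, "+", NULL, 30, "UNCLASSIFIED"),
    gene_design("SG25",  900, 1900, 0.40, "+", NULL, 30, "UNCLASSIFIED"),
    gene_design("SG26", 1300, 2100, 0.45, "-", NULL, 30, "UNCLASSIFIED"),
    gene_design("SG27", 1000, 2000, 0.50, "+", NULL, 30, "UNCLASSIFIED"),
    gene_design("SG28",  850, 2300, 0.55, "+", NULL, 30, "UNCLASSIFIED"),
    gene_design("SG29", 1150, 2500, 0.60, "-", NULL, 30, "UNCLASSIFIED"),
    gene_design("SG30", 1000, 2000, 0.66, "+", NULL, 30, "UNCLASSIFIED"))
  names(d) <- vapply(d, `[[`, "", "gene_id")
  d
}

# Assign genomic layout: sequential placement on one chromosome
.assign_layout <- function(designs, chrom = "sim1", gap = 5000L, origin = 1000L) {
  ids <- vapply(designs, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene_id in designs: ",
                               ids[duplicated(ids)][1])
  pos <- origin
  for (i in seq_along(designs)) {
    if (is.na(designs[[i]]$chrom)) {
      designs[[i]]$chrom <- chrom
      designs[[i]]$tx_start <- pos
    }
    pos <- max(pos, designs[[i]]$tx_start +
                 designs[[i]]$cds_length_bp + designs[[i]]$utr3_length_bp) + gap
  }
  # overlap check on each chromosome
  spans <- data.frame(
    chrom = vapply(designs, `[[`, "", "chrom"),
    start = vapply(designs, `[[`, 0L, "tx_start"),
    end = vapply(designs, function(d) d$tx_start + d$cds_length_bp + d$utr3_length_bp, 0L))
  for (ch in unique(spans$chrom)) {
    s <- spans[spans$chrom == ch, ]; s <- s[order(s$start), ]
    if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping designed genes on chromosome ", ch)
  }
  designs
}

# Genomic regions (BED-style) of a laid-out design
.design_geometry <- function(design) {
  t0 <- design$tx_start; Lc <- design$cds_length_bp; Lu <- design$utr3_length_bp
  if (design$strand == "+") {
    list(cds = c(t0, t0 + Lc), utr = c(t0 + Lc, t0 + Lc + Lu),
         junction = t0 + Lc, span = c(t0, t0 + Lc + Lu))
  } else {
    list(cds = c(t0 + Lu, t0 + Lu + Lc), utr = c(t0, t0 + Lu),
         junction = t0 + Lu, span = c(t0, t0 + Lc + Lu))
  }
}

#' Write designed gene models as GTF and BED12
#'
#' Lays the designs out on a synthetic chromosome (unless they already carry
#' coordinates), checks id uniqueness and non-overlap, and writes matching
#' `models.gtf` and `models.bed` files that round-trip through
#' [load_gene_models()].
#'
#' @param designs List of [gene_design()]s.
#' @param dir Output directory.
#' @return Invisibly, a list with the laid-out `designs`, in-memory
#'   `models` ([gene_model()] list) and the file `paths`.
#' @export
generate_gene_models <- function(designs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  designs <- .assign_layout(designs)
  gtf <- character(0); bed <- character(0); models <- list()
  for (d in designs) {
    g <- .design_geometry(d)
    L <- d$cds_length_bp + d$utr3_length_bp
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
                     d$gene_id, d$gene_id, d$gene_id)
    line <- function(type, s0, e) sprintf("%s\tisoutr_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                          d$chrom, type, s0 + 1L, e, d$strand, attrs)
    gtf <- c(gtf,
             line("gene", g$span[1], g$span[2]),
             line("transcript", g$span[1], g$span[2]),
             line("exon", g$span[1], g$span[2]),
             line("CDS", g$cds[1], g$cds[2]))
    bed <- c(bed, paste(d$chrom, g$span[1], g$span[2], d$gene_id, 0L, d$strand,
                        g$cds[1], g$cds[2], 0L, 1L,
                        paste0(L, ","), "0,", sep = "\t"))
    models[[d$gene_id]] <- gene_model(
      d$gene_id, d$chrom, d$strand,
      data.frame(start = g$cds[1], end = g$cds[2]),
      data.frame(start = g$utr[1], end = g$utr[2]))
  }
  gtf_path <- file.path(dir, "models.gtf"); bed_path <- file.path(dir, "models.bed")
  writeLines(gtf, gtf_path); writeLines(bed, bed_path)
  invisible(list(designs = designs, models = models,
                 paths = c(gtf = gtf_path, bed = bed_path)))
}

#' Simulate one replicate's coverage for one gene
#'
#' Expected depth at base i is `design_fpkm(i) * total_mapped_reads / 1e9`
#' (the inverse of [per_base_fpkm()]); noise is applied per base (Poisson),
#' per 50-bp tile (negative binomial) or not at all. Draws from the current
#' RNG stream unless `seed` is given.
#'
#' @param design A laid-out [gene_design()].
#' @param config A [simulation_config()].
#' @param replicate Replicate index (selects the library size).
#' @param seed Optional scoped seed.
#' @param check_fpkm_threshold Warn when a designed peak's FPKM does not
#'   exceed this detection threshold (default 100), reporting the margin.
#' @return List with transcript-oriented `cds_depth` and `utr_depth`,
#'   `counts` (`gene_id`, `region` in CDS/UTR3/GENE, `read_count`) and
#'   `total_mapped_reads`.
#' @export
simulate_coverage <- function(design, config, replicate = 1L, seed = NULL,
                              check_fpkm_threshold = 100) {
  lib <- config$library_size[replicate]
  prof <- expected_fpkm_profile(design)
  if (!is.null(design$peak_blueprints)) {
    margin <- min(design$peak_blueprints$design_fpkm) - check_fpkm_threshold
    if (margin <= 0)
      warning(sprintf("gene %s: designed peak FPKM leaves margin %.1f below the %.0f detection threshold",
                      design$gene_id, margin, check_fpkm_threshold))
  }
  draw <- function() {
    expected <- c(prof$cds, prof$utr) * lib / 1e9
    depth <- switch(config$noise,
      none = round(expected),
      poisson = stats::rpois(length(expected), expected),
      nb = {
        tiles <- ceiling(seq_along(expected) / 50)
        mult <- stats::rgamma(max(tiles), shape = 1 / config$nb_dispersion,
                              scale = config$nb_dispersion)
        stats::rpois(length(expected), expected * mult[tiles])
      })
    depth
  }
  depth <- if (is.null(seed)) draw() else {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed); draw()
  }
  Lc <- design$cds_length_bp
  cds_depth <- depth[seq_len(Lc)]
  utr_depth <- depth[-seq_len(Lc)]
  rl <- config$read_length
  counts <- data.frame(
    gene_id = design$gene_id,
    region = c("CDS", "UTR3", "GENE"),
    read_count = round(c(sum(cds_depth), sum(utr_depth), sum(depth)) / rl))
  list(cds_depth = cds_depth, utr_depth = utr_depth, counts = counts,
       total_mapped_reads = lib)
}

#' Simulate an EST set for one gene
#'
#' Classes are drawn from the configured mixture: `UTR_ONLY` fragments fall
#' uniformly inside the 3'UTR, `CDS_ONLY` inside the CDS, and `MIXED`
#' fragments are forced to straddle the CDS-3'UTR junction. Lengths are
#' uniform on 150-600 bp, clipped to the region.
#'
#' @param design A laid-out [gene_design()].
#' @param config A [simulation_config()].
#' @param n Number of ESTs (default `config$n_ests`).
#' @return `data.frame` of BED6 rows plus a `truth` label column.
#' @export
simulate_ests <- function(design, config, n = config$n_ests) {
  g <- .design_geometry(design)
  mix <- config$est_mixture
  min_len <- 150L
  req <- c(UTR_ONLY = mix[[1]], CDS_ONLY = mix[[2]], MIXED = mix[[3]]) > 0
  if (req["UTR_ONLY"] && design$utr3_length_bp < min_len)
    stop("3'UTR shorter than the minimum EST length for gene ", design$gene_id)
  if (req["CDS_ONLY"] && design$cds_length_bp < min_len)
    stop("CDS shorter than the minimum EST length for gene ", design$gene_id)
  cls <- sample(c("UTR_ONLY", "CDS_ONLY", "MIXED"), n, replace = TRUE,
                prob = mix)
  len <- sample(150:600, n, replace = TRUE)
  start <- integer(n)
  for (i in seq_len(n)) {
    if (cls[i] == "UTR_ONLY") {
      l <- min(len[i], design$utr3_length_bp)
      start[i] <- g$utr[1] + sample.int(g$utr[2] - g$utr[1] - l + 1L, 1L) - 1L
    } else if (cls[i] == "CDS_ONLY") {
      l <- min(len[i], design$cds_length_bp)
      start[i] <- g$cds[1] + sample.int(g$cds[2] - g$cds[1] - l + 1L, 1L) - 1L
    } else {
      l <- max(len[i], 2L)
      lo <- max(g$span[1], g$junction - l + 1L)
      hi <- min(g$junction - 1L, g$span[2] - l)
      start[i] <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    }
    len[i] <- min(len[i], g$span[2] - start[i])
  }
  data.frame(chrom = design$chrom, start = start, end = start + len,
             name = sprintf("%s|est%d", design$gene_id, seq_len(n)),
             score = 0L, strand = design$strand, truth = cls)
}

# Valley gaps of a design within the 3'UTR (spliced BED offsets)
.designed_valleys <- function(design) {
  pk <- designed_utr_peaks(design)
  Lu <- design$utr3_length_bp
  bounds <- c(0L, as.vector(t(pk[order(pk$start), c("start", "end")])), Lu)
  gaps <- matrix(bounds, ncol = 2, byrow = TRUE)  # (0,s1),(e1,s2),...,(ek,Lu)
  gaps <- gaps[gaps[, 2] > gaps[, 1], , drop = FALSE]
  data.frame(start = gaps[, 1], end = gaps[, 2])
}

# spliced UTR offset -> genomic BED interval (single-exon designs)
.spliced_to_genomic_design <- function(design, s, e) {
  g <- .design_geometry(design)
  if (design$strand == "+") c(g$utr[1] + s, g$utr[1] + e)
  else c(g$utr[2] - e, g$utr[2] - s)
}

#' Simulate element tracks for one gene
#'
#' miRNA-site elements are placed inside designed peaks; CpG islands, TF
#' clusters, H3K27ac and DNase elements inside designed valleys, preferring
#' the valley immediately 5' of a peak (transcript orientation) — the
#' configuration observed upstream of expressed 3'UTR peaks. Errors when a
#' requested category has no window that fits.
#'
#' @inheritParams simulate_ests
#' @param counts Named per-category counts (default
#'   `config$elements_per_category`).
#' @return `data.frame` of BED6 rows (`name` = category) plus `placed_in`
#'   truth column (`peak`/`valley`).
#' @export
.element_lengths <- c(miRNA_site = 22L, TF_cluster = 150L, CpG_island = 300L,
                      H3K27ac = 350L, DNase = 150L)

# categories of `counts` for which some designed peak/valley window fits
.feasible_element_counts <- function(design, counts) {
  pk <- designed_utr_peaks(design)
  vl <- .designed_valleys(design)
  feas <- vapply(names(counts), function(cat) {
    l <- if (cat %in% names(.element_lengths)) .element_lengths[[cat]] else 150L
    w <- if (cat == "miRNA_site") pk else vl
    nrow(w) > 0L && any(w$end - w$start >= l)
  }, logical(1))
  counts[feas]
}

simulate_elements <- function(design, config,
                              counts = config$elements_per_category) {
  lens <- .element_lengths
  pk <- designed_utr_peaks(design)
  vl <- .designed_valleys(design)
  rows <- list()
  place_in <- function(windows, l) {
    fits <- windows[windows$end - windows$start >= l, , drop = FALSE]
    if (nrow(fits) == 0L) return(NULL)
    w <- fits[sample.int(nrow(fits), 1L), ]
    if (w$end - w$start == l) s <- w$start
    else s <- w$start + sample.int(w$end - w$start - l + 1L, 1L) - 1L
    c(s, s + l)
  }
  for (cat in names(counts)) {
    k <- counts[[cat]]
    if (k < 1L) next
    l <- if (cat %in% names(lens)) lens[[cat]] else 150L
    windows <- if (cat == "miRNA_site") pk else {
      # prefer valleys that immediately precede a peak on the transcript
      pre <- vl[vl$end %in% pk$start, , drop = FALSE]
      if (nrow(pre) && any(pre$end - pre$start >= l)) pre else vl
    }
    for (i in seq_len(k)) {
      sp <- place_in(windows, l)
      if (is.null(sp))
        stop("no ", if (cat == "miRNA_site") "peak" else "valley",
             " window fits a ", cat, " element for gene ", design$gene_id)
      gg <- .spliced_to_genomic_design(design, sp[1], sp[2])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = design$chrom, start = gg[1], end = gg[2], name = cat,
        score = 0L, strand = design$strand,
        placed_in = if (cat == "miRNA_site") "peak" else "valley")
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Simulate a full dataset with ground truth
#'
#' Generates annotation (GTF + BED12), per-replicate bedGraph coverage with
#' matching read-count tables and library sizes, an EST BED, element BEDs
#' (for genes with designed peaks), and ground-truth tables, all under
#' `dir`. Identical seeds give byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @param designs Optional design list; defaults to the first
#'   `config$n_genes` of [default_gene_designs()].
#' @return Invisibly, list with `dir`, laid-out `designs`, `models`,
#'   `paths` (named file paths) and `truth` (data.frames).
#' @export
simulate_dataset <- function(config = simulation_config(), dir,
                             designs = NULL) {
  set.seed(config$seed)
  if (is.null(designs)) {
    designs <- default_gene_designs()
    if (config$n_genes > length(designs))
      stop("n_genes exceeds the default design set (", length(designs), ")")
    designs <- designs[seq_len(config$n_genes)]
  }
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)

  gm <- generate_gene_models(designs, dir)
  designs <- gm$designs

  # coverage + counts per replicate
  cov_paths <- counts_paths <- character(config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    bg_rows <- list(); cnt_rows <- list()
    for (d in designs) {
      sim <- simulate_coverage(d, config, r)
      depth_tx <- c(sim$cds_depth, sim$utr_depth)
      depth_gen <- if (d$strand == "+") depth_tx else rev(depth_tx)
      rl <- rle(as.numeric(depth_gen))
      ends <- cumsum(rl$lengths); starts <- ends - rl$lengths
      keep <- rl$values > 0
      if (any(keep)) {
        bg_rows[[length(bg_rows) + 1L]] <- data.frame(
          chrom = d$chrom, start = d$tx_start + starts[keep],
          end = d$tx_start + ends[keep], score = rl$values[keep])
      }
      cnt_rows[[length(cnt_rows) + 1L]] <- sim$counts
    }
    cov_paths[r] <- file.path(dir, "coverage", sprintf("rep%d.bedGraph", r))
    counts_paths[r] <- file.path(dir, "counts", sprintf("rep%d_counts.tsv", r))
    utils::write.table(do.call(rbind, bg_rows), cov_paths[r], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(do.call(rbind, cnt_rows), counts_paths[r], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  lib_path <- file.path(dir, "library_sizes.tsv")
  utils::write.table(
    data.frame(replicate_id = sprintf("rep%d", seq_len(config$n_replicates)),
               total_mapped_reads = config$library_size),
    lib_path, sep = "\t", quote = FALSE, row.names = FALSE)

  # ESTs
  est_rows <- lapply(designs, simulate_ests, config = config)
  ests <- do.call(rbind, est_rows)
  est_path <- file.path(dir, "ests.bed")
  utils::write.table(ests[c("chrom", "start", "end", "name", "score", "strand")],
                     est_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  est_truth <- data.frame(name = ests$name,
                          gene_id = sub("\\|.*$", "", ests$name),
                          truth = ests$truth)

  # elements for genes with designed peaks
  el_rows <- list()
  for (d in designs) {
    if (is.null(d$peak_blueprints)) next
    counts <- .feasible_element_counts(d, config$elements_per_category)
    if (!length(counts)) next
    el <- simulate_elements(d, config, counts = counts)
    if (!is.null(el)) { el$gene_id <- d$gene_id; el_rows[[d$gene_id]] <- el }
  }
  el_path <- NA_character_; el_truth <- NULL
  if (length(el_rows)) {
    els <- do.call(rbind, el_rows)
    el_path <- file.path(dir, "elements.bed")
    utils::write.table(els[c("chrom", "start", "end", "name", "score", "strand")],
                       el_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    el_truth <- els[c("gene_id", "name", "chrom", "start", "end", "placed_in")]
    names(el_truth)[2] <- "category"
  }

  # truth tables
  thr <- classification_params()
  design_truth <- do.call(rbind, lapply(designs, function(d) {
    pk <- designed_utr_peaks(d)
    data.frame(gene_id = d$gene_id, chrom = d$chrom, tx_start = d$tx_start,
               strand = d$strand, cds_length_bp = d$cds_length_bp,
               utr3_length_bp = d$utr3_length_bp,
               designed_ratio = d$designed_ratio,
               truth_class = as.character(classify_gene(d$designed_ratio, TRUE, thr)),
               pattern_type_truth = d$pattern_type_truth,
               n_peaks_truth = nrow(pk))
  }))
  peak_truth <- do.call(rbind, lapply(designs, function(d) {
    pk <- designed_utr_peaks(d)
    if (nrow(pk) == 0L) return(NULL)
    gen <- t(vapply(seq_len(nrow(pk)), function(i)
      .spliced_to_genomic_design(d, pk$start[i], pk$end[i]), numeric(2)))
    data.frame(gene_id = d$gene_id, peak_index = seq_len(nrow(pk)),
               spliced_start = pk$start, spliced_end = pk$end,
               genomic_start = gen[, 1], genomic_end = gen[, 2])
  }))
  truth_paths <- c(designs = file.path(dir, "truth", "designs.tsv"),
                   peaks = file.path(dir, "truth", "peak_truth.tsv"),
                   ests = file.path(dir, "truth", "est_truth.tsv"))
  utils::write.table(design_truth, truth_paths["designs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(peak_truth, truth_paths["peaks"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(est_truth, truth_paths["ests"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(el_truth)) {
    truth_paths["elements"] <- file.path(dir, "truth", "element_truth.tsv")
    utils::write.table(el_truth, truth_paths["elements"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  invisible(list(
    dir = dir, designs = designs, models = gm$models, config = config,
    paths = list(annotation = gm$paths[["gtf"]], bed12 = gm$paths[["bed"]],
                 coverage = cov_paths, counts = counts_paths,
                 library_sizes = lib_path, ests = est_path,
                 elements = el_path, truth = truth_paths),
    truth = list(designs = design_truth, peaks = peak_truth,
                 ests = est_truth, elements = el_truth)))
}
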