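# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A simple plus-strand gene: CDS [100,400), 3'UTR [400,1000) (BED-style)
toy_model <- function(strand = "+") {
  if (strand == "+") {
    gene_model("toy", "chr1", "+",
               data.frame(start = 100, end = 400),
               data.frame(start = 400, end = 1000))
  } else {
    # mirrored: 3'UTR [100,600), CDS [600,900)
    gene_model("toy", "chr1", "-",
               data.frame(start = 600, end = 900),
               data.frame(start = 100, end = 600))
  }
}

# Write a SAM text file and convert to an indexed BAM.
# reads: data.frame(qname, chrom, pos1 (1-based), len, mapq)
toy_bam <- function(reads, chrom_len = c(chr1 = 2000), dir = tempdir()) {
  sam <- file.path(dir, paste0("toy-", as.integer(stats::runif(1, 1, 1e8)), ".sam"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len), chrom_len))
  reads <- reads[order(reads$chrom, reads$pos1), ]
  # SEQ must match CIGAR length
  body <- sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                  reads$qname, reads$chrom, reads$pos1, reads$mapq, reads$len,
                  vapply(reads$len, function(l) strrep("A", l), ""))
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam), overwrite = TRUE)
  bam
}

# Brute-force per-base depth oracle: iterate reads x positions
brute_depth <- function(reads, from1, to1) {
  depth <- integer(to1 - from1 + 1L)
  for (i in seq_len(nrow(reads))) {
    for (p in seq(reads$pos1[i], reads$pos1[i] + reads$len[i] - 1L)) {
      if (p >= from1 && p <= to1) depth[p - from1 + 1L] <- depth[p - from1 + 1L] + 1L
    }
  }
  depth
}

# Brute-force consensus peak oracle: explicit boolean matrix + run scan
brute_peaks <- function(fpkm, threshold, min_run, min_rep) {
  ok <- rowSums(fpkm > threshold) >= min_rep
  out <- list(); i <- 1L; n <- length(ok)
  while (i <= n) {
    if (ok[i]) {
      j <- i
      while (j < n && ok[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_run)
        out[[length(out) + 1L]] <- c(start = i - 1L, end = j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  as.data.frame(do.call(rbind, out))
}

# Random block-structured FPKM matrix exercising threshold/run boundaries
random_fpkm_matrix <- function(len, n_rep, threshold = 100) {
  n_blocks <- sample(3:10, 1)
  cuts <- sort(c(0L, sample.int(len - 1L, n_blocks - 1L), len))
  base <- numeric(len)
  for (b in seq_len(n_blocks)) {
    lvl <- sample(c(0, threshold * 0.5, threshold, threshold * 1.5, threshold * 3), 1)
    if (cuts[b + 1L] > cuts[b]) base[(cuts[b] + 1L):cuts[b + 1L]] <- lvl
  }
  m <- vapply(seq_len(n_rep), function(r)
    pmax(base + stats::rnorm(len, 0, threshold * 0.2), 0), numeric(len))
  matrix(m, nrow = len)
}

# Default small simulated dataset + pipeline run, shared across test files
small_sim <- function() {
  cached("small_sim", {
    cfg <- simulation_config(n_genes = 6, seed = 101)
    sim <- simulate_dataset(cfg, file.path(tempdir(), "isoutr-small-sim"))
    list(cfg = cfg, sim = sim)
  })
}
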