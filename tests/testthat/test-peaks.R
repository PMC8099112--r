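test_that("per-base FPKM treats each base as a 1-bp feature", {
  expect_equal(per_base_fpkm(rep(1, 10), 1e9), rep(1, 10))
  expect_equal(per_base_fpkm(rep(2, 10), 2e9), rep(1, 10))  # library scaling cancels
  expect_equal(per_base_fpkm(5, 1e7), 500)
})

test_that("consensus peaks honour the strict run-length and threshold bounds", {
  p <- peak_params()
  mk <- function(run_len, n_above_reps = 4, total = 1000, start = 100,
                 level = 200) {
    m <- matrix(50, nrow = total, ncol = 4)
    for (r in seq_len(n_above_reps))
      m[(start + 1):(start + run_len), r] <- level
    m
  }
  # 200-bp run above threshold in all 4 replicates -> one peak of length 200
  pk <- call_consensus_peaks(mk(200), p)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$start, pk$end), c(100, 300))
  expect_equal(pk$n_supporting_replicates, 4L)
  # 151 bp is the shortest admissible run; 150 is not (>150 bp, strict)
  expect_equal(nrow(call_consensus_peaks(mk(151), p)), 1)
  expect_equal(nrow(call_consensus_peaks(mk(150), p)), 0)
  # FPKM exactly at the threshold does not count (strict >)
  expect_equal(nrow(call_consensus_peaks(mk(200, level = 100), p)), 0)
  expect_equal(nrow(call_consensus_peaks(mk(200, level = 100 + 1e-9), p)), 1)
  # above threshold in only 3 of 4 replicates -> no peak under the all-replicates rule
  expect_equal(nrow(call_consensus_peaks(mk(200, n_above_reps = 3), p)), 0)
  expect_equal(nrow(call_consensus_peaks(mk(200, n_above_reps = 3),
                                         peak_params(min_replicates = 3))), 1)
})

test_that("replicate arrays of unequal length are rejected", {
  expect_error(call_consensus_peaks(list(rep(200, 100), rep(200, 99))),
               "same length")
})

test_that("peak calls match the brute-force boolean-matrix oracle", {
  p <- peak_params()
  set.seed(21)
  for (i in 1:200) {
    len <- sample(300:4000, 1)
    n_rep <- sample(1:6, 1)
    m <- random_fpkm_matrix(len, n_rep)
    got <- call_consensus_peaks(m, p)
    want <- brute_peaks(m, p$fpkm_threshold, p$min_run_bp, n_rep)
    expect_equal(got[c("start", "end")], want[c("start", "end")],
                 ignore_attr = TRUE)
  }
})

test_that("valleys are the long runs at or below the threshold", {
  p <- peak_params()
  # uniformly sub-threshold 1 kb 3'UTR -> one valley covering it all
  v <- call_valleys(matrix(50, 1000, 4), p)
  expect_equal(c(v$start, v$end), c(0, 1000))
  # two 300-bp peaks separated by a 400-bp gap -> the gap is the only interior valley
  m <- matrix(300, nrow = 1000, ncol = 4)
  m[301:700, ] <- 50
  v2 <- call_valleys(m, p)
  expect_equal(c(v2$start, v2$end), c(300, 700))
  # a 100-bp gap is too short to be a valley
  m3 <- matrix(300, nrow = 700, ncol = 4)
  m3[301:400, ] <- 50
  expect_equal(nrow(call_valleys(m3, p)), 0)
  # FPKM exactly at the threshold belongs to the valley side (<=)
  m4 <- matrix(100, 500, 4)
  expect_equal(nrow(call_valleys(m4, p)), 1)
})

test_that("peaks and valleys partition decided bases without overlap", {
  set.seed(22)
  p <- peak_params()
  for (i in 1:25) {
    m <- random_fpkm_matrix(sample(500:3000, 1), 4)
    pk <- call_consensus_peaks(m, p)
    vl <- call_valleys(m, p)
    in_peak <- in_valley <- logical(nrow(m))
    for (j in seq_len(nrow(pk))) in_peak[(pk$start[j] + 1):pk$end[j]] <- TRUE
    for (j in seq_len(nrow(vl))) in_valley[(vl$start[j] + 1):vl$end[j]] <- TRUE
    expect_false(any(in_peak & in_valley))
  }
})

test_that("peak calls are invariant to scaling depth and library size together", {
  set.seed(23)
  depth <- matrix(rpois(4000, 8), ncol = 4)
  lib <- 5e7
  p <- peak_params()
  f1 <- apply(depth, 2, per_base_fpkm, total_mapped_reads = lib)
  f2 <- apply(depth * 13, 2, per_base_fpkm, total_mapped_reads = lib * 13)
  expect_equal(call_consensus_peaks(f1, p), call_consensus_peaks(f2, p))
})

test_that("base-wise and interval-wise consensus differ as documented", {
  # with min_replicates=1, bases passing in different replicates can chain
  # into one run under base consensus but not under interval consensus
  m <- matrix(0, nrow = 400, ncol = 2)
  m[1:100, 1] <- 200     # run of 100 in rep1 (< 151)
  m[101:400, 2] <- 200   # run of 300 in rep2
  p_base <- peak_params(min_replicates = 1, consensus = "base")
  p_int <- peak_params(min_replicates = 1, consensus = "interval")
  pk_base <- call_consensus_peaks(m, p_base)
  pk_int <- call_consensus_peaks(m, p_int)
  expect_equal(c(pk_base$start, pk_base$end), c(0, 400))
  expect_equal(c(pk_int$start, pk_int$end), c(100, 400))
  # under the default all-replicates rule the two agree on random matrices
  set.seed(24)
  for (i in 1:10) {
    mm <- random_fpkm_matrix(1500, 4)
    expect_equal(call_consensus_peaks(mm, peak_params(consensus = "base")),
                 call_consensus_peaks(mm, peak_params(consensus = "interval")))
  }
})

test_that("pattern typing distinguishes the three archetypes", {
  p <- peak_params()
  mat <- function(v) matrix(rep(v, 4), ncol = 4)
  # TYPE_I: two internal UTR peaks with a valley between, quiet CDS
  utr <- rep(20, 3000); utr[301:800] <- 400; utr[1801:2300] <- 400
  t1 <- classify_pattern(mat(rep(50, 1000)), mat(utr), p)
  expect_equal(t1$pattern_type, "TYPE_I")
  expect_equal(nrow(t1$utr_peaks), 2)
  # TYPE_II: single peak starting 40 bp before the junction, short UTR
  cds <- rep(50, 900); cds[861:900] <- 400
  utr2 <- rep(400, 700); utr2[601:700] <- 20
  t2 <- classify_pattern(mat(cds), mat(utr2), p)
  expect_equal(t2$pattern_type, "TYPE_II")
  # TYPE_III: long UTR, CDS hot only in its terminal 10%
  cds3 <- rep(30, 800); cds3[721:800] <- 400
  utr3 <- rep(20, 2400); utr3[1:800] <- 400
  t3 <- classify_pattern(mat(cds3), mat(utr3), p)
  expect_equal(t3$pattern_type, "TYPE_III")
  # no peaks anywhere -> UNCLASSIFIED
  t0 <- classify_pattern(mat(rep(30, 800)), mat(rep(20, 2400)), p)
  expect_equal(t0$pattern_type, "UNCLASSIFIED")
  # CDS hot along its whole length disqualifies TYPE_III
  cds4 <- rep(400, 800)
  t4 <- classify_pattern(mat(cds4), mat(utr3), p)
  expect_equal(t4$pattern_type, "UNCLASSIFIED")
})

test_that("peak projection maps spliced offsets across UTR exons", {
  m <- gene_model("g", "chr1", "+",
                  data.frame(start = 100, end = 400),
                  data.frame(start = c(400, 900), end = c(700, 1200)))
  # spliced UTR: [400,700) then [900,1200); peak [200,400) spans the junction
  g <- project_to_genomic(m, data.frame(start = 200, end = 400))[[1]]
  expect_equal(GenomicRanges::start(g) - 1L, c(600, 900))
  expect_equal(GenomicRanges::end(g), c(700, 1000))

  # minus strand: spliced coordinates run genomically right-to-left
  mm <- gene_model("g2", "chr1", "-",
                   data.frame(start = 900, end = 1200),
                   data.frame(start = 100, end = 900))
  gm <- project_to_genomic(mm, data.frame(start = 0, end = 100))[[1]]
  expect_equal(GenomicRanges::start(gm) - 1L, 800)
  expect_equal(GenomicRanges::end(gm), 900)
})
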