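# toy gene: CDS [100,400), 3'UTR [400,1000), junction 400 (BED-style)

.frag <- function(start, end) data.frame(start = start, end = end)

test_that("fragment classification partitions UTR-only/CDS-only/mixed/outside", {
  m <- toy_model("+")
  expect_equal(as.character(classify_fragments(.frag(500, 800), m)), "UTR_ONLY")
  expect_equal(as.character(classify_fragments(.frag(150, 300), m)), "CDS_ONLY")
  expect_equal(as.character(classify_fragments(.frag(350, 450), m)), "MIXED")
  expect_equal(as.character(classify_fragments(.frag(2000, 2100), m)), "OUTSIDE")
  # vectorised: exactly one label each
  cls <- classify_fragments(.frag(c(500, 150, 350, 1500), c(800, 300, 450, 1600)), m)
  expect_false(anyNA(cls))
})

test_that("the junction base belongs to the 3'UTR side (half-open boundary)", {
  m <- toy_model("+")
  # fragment ending exactly at the junction never reaches the UTR
  expect_equal(as.character(classify_fragments(.frag(300, 400), m)), "CDS_ONLY")
  # fragment starting exactly at the junction never reaches the CDS
  expect_equal(as.character(classify_fragments(.frag(400, 500), m)), "UTR_ONLY")
  # one base over in each direction flips to MIXED
  expect_equal(as.character(classify_fragments(.frag(399, 401), m)), "MIXED")
})

test_that("a larger min_overlap_bp demotes grazing overlaps", {
  m <- toy_model("+")
  # 10 bp in CDS, 40 bp in UTR
  expect_equal(as.character(classify_fragments(.frag(390, 440), m)), "MIXED")
  expect_equal(as.character(classify_fragments(.frag(390, 440), m,
                                               min_overlap_bp = 20)), "UTR_ONLY")
})

test_that("EST summary counts, fractions and junction bins are correct", {
  m <- toy_model("+")
  frs <- .frag(
    start = c(410, 450, 500, 550, 600, 650, 700, 750,  150,  350, 1500),
    end   = c(460, 520, 560, 610, 660, 710, 760, 810,  220,  450, 1600))
  # 8 UTR-only, 1 CDS-only, 1 mixed, 1 outside
  s <- summarize_ests(frs, m)
  expect_equal(s$summary$n_total, 10)
  expect_equal(s$summary$n_outside, 1)
  expect_equal(s$summary$frac_utr_only, 0.8)
  expect_equal(s$summary$frac_cds_only, 0.1)
  expect_equal(s$summary$frac_mixed, 0.1)
  expect_equal(s$summary$frac_utr_only + s$summary$frac_cds_only +
                 s$summary$frac_mixed, 1)
  # bin -1 = [150,400): overlapped by the CDS-only EST and the mixed EST
  b <- s$bins
  expect_equal(b$n_overlapping[b$offset == -1], 2)
  # bin +1 = [400,650): the mixed EST + the five UTR ESTs starting before 650
  expect_equal(b$n_overlapping[b$offset == 1],
               sum(frs$start < 650 & frs$end > 400))
})

test_that("two ESTs ending exactly at the junction produce zero MIXED", {
  m <- toy_model("+")
  s <- summarize_ests(.frag(c(300, 350), c(400, 400)), m)
  expect_equal(s$summary$n_mixed, 0)
  expect_equal(s$summary$n_cds_only, 2)
})

test_that("valley-spanning ESTs require covering the whole internal valley", {
  m <- toy_model("+")
  # spliced UTR valley [400,800) -> genomic [800,1200)?  UTR starts at 400:
  # spliced offset 400 = genomic 800. peaks flank it.
  ps <- structure(list(gene_id = "toy",
                       peaks = data.frame(start = c(0, 500), end = c(200, 600)),
                       valleys = data.frame(start = 200, end = 500)),
                  class = "PeakSet")
  # genomic valley = [600,900); EST [550,950) covers it, [550,800) does not
  s1 <- summarize_ests(.frag(550, 950), m, ps)
  expect_equal(s1$summary$n_spanning_internal_valley, 1)
  s2 <- summarize_ests(.frag(550, 800), m, ps)
  expect_equal(s2$summary$n_spanning_internal_valley, 0)
  # leading/trailing valleys are not internal
  ps2 <- structure(list(gene_id = "toy",
                        peaks = data.frame(start = 500, end = 700),
                        valleys = data.frame(start = 0, end = 500)),
                   class = "PeakSet")
  s3 <- summarize_ests(.frag(350, 950), m, ps2)
  expect_equal(s3$summary$n_spanning_internal_valley, 0)
})

.toy_peakset <- function() {
  # peaks at spliced [0,200) and [400,600) -> genomic [400,600), [800,1000)
  structure(list(gene_id = "toy",
                 peaks = data.frame(start = c(0, 400), end = c(200, 600)),
                 valleys = data.frame(start = 200, end = 400)),
            class = "PeakSet")
}

test_that("elements are assigned to peaks/valleys/elsewhere by midpoint", {
  m <- toy_model("+")
  els <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(451, 851, 651, 151, 1500), width = 20))
  els$category <- c("miRNA_site", "miRNA_site", "CpG", "TF", "TF")
  ov <- element_overlap(els, .toy_peakset(), m)
  mi <- ov[ov$category == "miRNA_site", ]
  expect_equal(mi$n_in_peaks, 2)
  expect_equal(mi$peak_fraction, 1.0)
  expect_equal(ov$n_in_valleys[ov$category == "CpG"], 1)
  tf <- ov[ov$category == "TF", ]
  expect_equal(tf$n_elsewhere, 1)       # midpoint in the CDS
  expect_equal(tf$n_outside_span, 1)    # beyond the gene span, excluded
  expect_equal(tf$peak_fraction, 0)
})

test_that("a long element spanning a peak edge is assigned by its midpoint", {
  m <- toy_model("+")
  # element [550,750): overlaps peak1 end but midpoint 650 sits in the valley
  el <- GenomicRanges::GRanges("chr1", IRanges::IRanges(551, 750))
  el$category <- "H3K27ac"
  ov <- element_overlap(el, .toy_peakset(), m)
  expect_equal(ov$n_in_valleys, 1)
  ov2 <- element_overlap(el, .toy_peakset(), m, mode = "any")
  expect_equal(ov2$n_in_peaks, 1)
})

test_that("permutation test is seeded, bounded and flags degenerate peaks", {
  m <- toy_model("+")
  ps <- .toy_peakset()
  els <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(421, 471, 521, 821, 871), width = 22))
  els$category <- "miRNA_site"
  r1 <- element_permutation_test(els, ps, m, n_perm = 999, seed = 5)
  r2 <- element_permutation_test(els, ps, m, n_perm = 999, seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$observed_peak_fraction, 1)
  # peaks cover ~44% of the 900-bp span; null exceedance per permutation is
  # at most ~0.45^5 ~ 0.018, so p should be small for 5 concentrated sites
  expect_lt(r1$empirical_p, 0.1)
  expect_gte(r1$empirical_p, 1 / 1000)

  # peaks covering the whole 3'UTR leave only the CDS as background: the
  # test still runs, but concentration inside peaks is no longer surprising
  ps_all <- structure(list(gene_id = "toy",
                           peaks = data.frame(start = 0, end = 600),
                           valleys = data.frame(start = integer(0),
                                                end = integer(0))),
                      class = "PeakSet")
  rd <- element_permutation_test(els, ps_all, m, n_perm = 199, seed = 1)
  expect_gt(rd$empirical_p, r1$empirical_p)

  expect_error(element_permutation_test(els, ps, m, n_perm = 0), "n_perm")
  expect_error(element_permutation_test(els[0], ps, m, n_perm = 10),
               "at least one")
})

test_that("element BED reader takes the category from name or 7th column", {
  dir <- withr::local_tempdir()
  p6 <- file.path(dir, "e6.bed")
  writeLines(c("chr1\t100\t200\tCpG\t0\t+", "chr1\t300\t400\tmiRNA_site\t0\t+"), p6)
  g6 <- read_elements_bed(p6)
  expect_equal(g6$category, c("CpG", "miRNA_site"))
  p7 <- file.path(dir, "e7.bed")
  writeLines("chr1\t100\t200\tel1\t0\t+\tH3K27ac", p7)
  expect_equal(read_elements_bed(p7)$category, "H3K27ac")
})
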