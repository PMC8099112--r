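test_that("gene designs validate blueprints and solve the CDS baseline", {
  expect_error(gene_design("g", 900, 700, 0.8,
                           peak_blueprints = data.frame(offset_bp = c(100, 150),
                                                        length_bp = c(200, 200),
                                                        design_fpkm = c(400, 400))),
               "disjoint")
  expect_error(gene_design("g", 900, 700, 0.8,
                           peak_blueprints = data.frame(offset_bp = 500,
                                                        length_bp = 300,
                                                        design_fpkm = 400)),
               "outside")
  # a tiny designed ratio cannot absorb a large junction-spanning peak
  expect_error(gene_design("g", 200, 2000, 0.99,
                           peak_blueprints = data.frame(offset_bp = -150,
                                                        length_bp = 1000,
                                                        design_fpkm = 500)),
               "incompatible")

  # the noise-free profile reproduces the designed ratio exactly
  for (r in c(0.1, 0.4, 0.66, 0.9)) {
    d <- gene_design("g", 1000, 2500, r,
                     peak_blueprints = data.frame(offset_bp = 300,
                                                  length_bp = 500,
                                                  design_fpkm = 400))
    prof <- expected_fpkm_profile(d)
    expect_equal(mean(prof$utr) / (mean(prof$utr) + mean(prof$cds)), r,
                 tolerance = 1e-12)
  }
})

test_that("designed FPKM converts to expected depth via the per-base formula", {
  d <- gene_design("g", 500, 1500, 0.8,
                   peak_blueprints = data.frame(offset_bp = 200, length_bp = 400,
                                                design_fpkm = 200))
  cfg <- simulation_config(n_replicates = 1, library_size = 1e8,
                           noise = "none", seed = 1)
  d$chrom <- "sim1"; d$tx_start <- 1000L
  sim <- simulate_coverage(d, cfg, 1)
  # design 200 FPKM at 1e8 reads -> depth 20 inside the peak
  expect_equal(unique(sim$utr_depth[201:600]), 20)
  expect_equal(sim$total_mapped_reads, 1e8)
  # noise-free depth equals the rounded expected profile everywhere
  prof <- expected_fpkm_profile(d)
  expect_equal(sim$utr_depth, round(prof$utr * 1e8 / 1e9))
  expect_equal(sim$cds_depth, round(prof$cds * 1e8 / 1e9))
})

test_that("a designed peak at or below the detection threshold warns", {
  d <- gene_design("g", 500, 1500, 0.8,
                   peak_blueprints = data.frame(offset_bp = 200, length_bp = 400,
                                                design_fpkm = 90))
  d$chrom <- "sim1"; d$tx_start <- 1000L
  cfg <- simulation_config(n_replicates = 1, library_size = 1e8, seed = 1)
  expect_warning(simulate_coverage(d, cfg, 1), "margin")
})

test_that("generated annotation files round-trip through load_gene_models", {
  s <- small_sim()
  models_gtf <- load_gene_models(s$sim$paths$annotation)
  models_bed <- load_gene_models(s$sim$paths$bed12)
  expect_setequal(names(models_gtf), names(s$sim$models))
  for (gid in names(models_gtf)) {
    expect_equal(as.data.frame(models_gtf[[gid]]$cds),
                 as.data.frame(s$sim$models[[gid]]$cds))
    expect_equal(as.data.frame(models_gtf[[gid]]$utr3),
                 as.data.frame(models_bed[[gid]]$utr3))
    expect_equal(models_gtf[[gid]]$junction, models_bed[[gid]]$junction)
  }
})

test_that("identical seeds give byte-identical datasets; seeds differ otherwise", {
  cfg <- simulation_config(n_genes = 3, seed = 55)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  d3 <- file.path(tempdir(), "det3"); unlink(d3, recursive = TRUE)
  simulate_dataset(simulation_config(n_genes = 3, seed = 56), d3)
  cov1 <- tools::md5sum(file.path(d1, "coverage", "rep1.bedGraph"))
  cov3 <- tools::md5sum(file.path(d3, "coverage", "rep1.bedGraph"))
  expect_false(unname(cov1) == unname(cov3))
})

test_that("duplicate gene ids and overlapping layouts are rejected", {
  d1 <- gene_design("dup", 500, 1500, 0.5)
  d2 <- gene_design("dup", 500, 1500, 0.5)
  expect_error(generate_gene_models(list(d1, d2), tempdir()), "duplicate")
  a <- gene_design("ga", 500, 1500, 0.5); a$chrom <- "sim1"; a$tx_start <- 1000L
  b <- gene_design("gb", 500, 1500, 0.5); b$chrom <- "sim1"; b$tx_start <- 1500L
  expect_error(generate_gene_models(list(a, b), tempdir()), "overlapping")
})

test_that("pure EST mixtures close the loop through classify_fragments", {
  d <- gene_design("g", 900, 1200, 0.7)
  d$chrom <- "sim1"; d$tx_start <- 1000L
  m <- gene_model("g", "sim1", "+",
                  data.frame(start = 1000, end = 1900),
                  data.frame(start = 1900, end = 3100))
  cfg_u <- simulation_config(est_mixture = c(1, 0, 0), n_ests = 50, seed = 3)
  set.seed(3)
  eu <- simulate_ests(d, cfg_u)
  cls <- classify_fragments(data.frame(start = eu$start, end = eu$end), m)
  expect_true(all(cls == "UTR_ONLY"))

  cfg_m <- simulation_config(est_mixture = c(0, 0, 1), n_ests = 10, seed = 3)
  set.seed(3)
  em <- simulate_ests(d, cfg_m)
  clm <- classify_fragments(data.frame(start = em$start, end = em$end), m)
  expect_true(all(clm == "MIXED"))

  # a 3'UTR shorter than the minimum EST length cannot host UTR_ONLY ESTs
  tiny <- gene_design("t", 900, 100, 0.7)
  tiny$chrom <- "sim1"; tiny$tx_start <- 1000L
  expect_error(simulate_ests(tiny, cfg_u), "shorter")
})

test_that("mixture fractions at n = 200 stay inside the binomial 95% interval", {
  d <- gene_design("g", 900, 2400, 0.7)
  d$chrom <- "sim1"; d$tx_start <- 1000L
  cfg <- simulation_config(n_ests = 200, seed = 9)
  set.seed(9)
  ests <- simulate_ests(d, cfg)
  n <- nrow(ests)
  for (cls in c("UTR_ONLY", "CDS_ONLY", "MIXED")) {
    p <- switch(cls, UTR_ONLY = 0.85, CDS_ONLY = 0.05, MIXED = 0.10)
    k <- sum(ests$truth == cls)
    expect_gte(k, qbinom(0.025, n, p))
    expect_lte(k, qbinom(0.975, n, p))
  }
})

test_that("simulated elements land in designed peaks and valleys", {
  s <- small_sim()
  truth <- s$sim$truth$elements
  models <- s$sim$models
  peaks <- s$sim$truth$peaks
  for (i in seq_len(nrow(truth))) {
    mid <- truth$start[i] + (truth$end[i] - truth$start[i] - 1) %/% 2
    pk <- peaks[peaks$gene_id == truth$gene_id[i], ]
    in_peak <- any(mid >= pk$genomic_start & mid < pk$genomic_end)
    expect_equal(in_peak, truth$placed_in[i] == "peak",
                 label = paste(truth$gene_id[i], truth$category[i]))
  }
  # miRNA sites in peaks, regulatory marks in valleys
  expect_true(all(truth$placed_in[truth$category == "miRNA_site"] == "peak"))
  expect_true(all(truth$placed_in[truth$category != "miRNA_site"] == "valley"))
})

test_that("elements cannot be placed where no window fits", {
  # gene whose single blueprint fills the whole 3'UTR: no valley space
  d <- gene_design("g", 900, 600, 0.8,
                   peak_blueprints = data.frame(offset_bp = 0, length_bp = 600,
                                                design_fpkm = 400))
  d$chrom <- "sim1"; d$tx_start <- 1000L
  cfg <- simulation_config(seed = 1)
  expect_error(simulate_elements(d, cfg, counts = c(CpG_island = 1)),
               "no valley window")
  # and no peaks at all: miRNA sites impossible
  flat <- gene_design("f", 900, 600, 0.5)
  flat$chrom <- "sim1"; flat$tx_start <- 1000L
  expect_error(simulate_elements(flat, cfg, counts = c(miRNA_site = 1)),
               "no peak window")
})

test_that("the default design set spans the documented conditions", {
  designs <- default_gene_designs()
  expect_length(designs, 30)
  ratios <- vapply(designs, `[[`, 0, "designed_ratio")
  expect_equal(range(ratios), c(0.05, 0.95))
  types <- vapply(designs, `[[`, "", "pattern_type_truth")
  expect_setequal(unique(types), c("TYPE_I", "TYPE_II", "TYPE_III", "UNCLASSIFIED"))
  # every designed peak is detectable at twice the default threshold
  for (d in designs) {
    if (is.null(d$peak_blueprints)) next
    expect_true(all(d$peak_blueprints$design_fpkm >= 200))
    # CDS baseline stays below the peak threshold so patterns stay clean
    expect_lt(d$cds_base_fpkm, 100)
  }
  # noise-free profiles reproduce the designed pattern types
  p <- peak_params()
  for (d in designs) {
    prof <- expected_fpkm_profile(d)
    pat <- classify_pattern(matrix(rep(prof$cds, 4), ncol = 4),
                            matrix(rep(prof$utr, 4), ncol = 4), p)
    expect_equal(pat$pattern_type, d$pattern_type_truth, label = d$gene_id)
  }
})
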