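# isoutr

Transcriptome-wide analysis of **isolated 3'UTR (i3'UTR) expression** from
RNA-seq coverage.

Mature mRNAs are expected to carry a 5'UTR, a coding region (CDS) and a
3'UTR at matched levels, yet many genes stably express their 3'UTR in the
absence — or far in excess — of the cognate CDS. `isoutr` quantifies this
from bulk RNA-seq alignments or coverage tracks, for people studying
non-coding RNA function, developmental transitions or cell-state changes:

* **Per-region expression.** For each gene's CDS and 3'UTR:

  `expression = reads / ((effective length in kb) x (total mapped reads in millions))`

  where the *effective length* is the number of bases with non-zero
  coverage, and a gene is *expressed* at >= 5 total mapped reads.

* **Fractional ratio and Hi/Lo classes.** The statistic
  `r = UTR / (UTR + CDS)` ranges from 0 (all expression in the CDS) to 1
  (all in the 3'UTR). Expressed genes with `r > 0.6` are **Hi 3'UTR**,
  `r < 0.4` **Lo 3'UTR** (Hi CDS); replicate concordance of the Hi set is
  reported as percent identity (Jaccard by default). Ranked Hi/Lo gene
  lists are exported for any downstream enrichment service.

* **Consensus peaks and valleys.** Within each (spliced) 3'UTR, a *peak*
  is a continuous run of more than 150 bp whose per-base FPKM exceeds 100
  in every replicate; *valleys* are the complementary runs. Each gene's
  peak architecture is typed: multiple discrete internal peaks with
  valleys (type i), a CDS-contiguous peak running into a short 3'UTR
  (type ii), or a long 3'UTR with a short leading CDS stretch (type iii).

* **ESTs and genomic elements.** cDNA fragments are classified as
  3'UTR-only / CDS-only / junction-spanning with a 250-bp junction-bin
  profile, and element tracks (CpG islands, TF clusters, miRNA sites,
  H3K27ac, DNase) are aligned to peaks versus valleys with a
  length-preserving permutation null.

* **Synthetic data with ground truth.** A seeded generator produces
  annotation, replicate coverage (Poisson or negative-binomial noise),
  EST sets and element tracks for designed gene architectures, so the
  whole pipeline is testable end to end without downloads.

## Worked example

```r
library(isoutr)

cfg <- simulation_config(n_genes = 6, seed = 101)   # 4 replicates, ~100M reads
sim <- simulate_dataset(cfg, "sim")
rc  <- run_config(annotation    = sim$paths$annotation,
                  coverage      = sim$paths$coverage,
                  library_sizes = cfg$library_size,
                  counts        = sim$paths$counts,
                  ests          = sim$paths$ests,
                  elements      = sim$paths$elements,
                  seed = 101)
res <- run_pipeline(rc, "out")
res$pooled[, c("gene_id", "ratio", "klass")]
```

```
  gene_id     ratio  klass
1    SG01 0.6997239 HI_UTR
2    SG02 0.7518382 HI_UTR
3    SG03 0.8005560 HI_UTR
4    SG04 0.8504222 HI_UTR
5    SG05 0.8987412 HI_UTR
6    SG06 0.9471477 HI_UTR
```

These six genes were designed with true 3'UTR shares 0.70-0.95; the pooled
fractional ratios land within ~0.005 of the design and all six are called
Hi 3'UTR. `res$patterns` shows each gene's recovered peak count and
pattern type (here: two to three internal peaks, type i), `out/peaks.bed`
and `out/valleys.bed` hold the genomic peak/valley projections, and
`out/element_overlap.tsv` shows the simulated miRNA sites falling entirely
inside peaks (`peak_fraction = 1`) with permutation p-values ~0.01-0.04.

The same stages are callable individually (`load_gene_models()`,
`quantify_regions()`, `gene_ratio_table()`, `call_consensus_peaks()`,
`classify_pattern()`, `summarize_ests()`, `element_overlap()`), and
`inst/scripts/isoutr` wraps `simulate` / `run-all` for shell use.

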