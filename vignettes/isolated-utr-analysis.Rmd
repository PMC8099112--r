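---
title: "Quantifying isolated 3'UTR expression: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying isolated 3'UTR expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoutr)
```

## The problem and the model

Many genes stably express their 3'UTR without the cognate coding sequence
(an *isolated 3'UTR*, i3'UTR), or the reverse. Given per-replicate RNA-seq
alignments or coverage and a gene annotation, `isoutr` quantifies this in
three layers.

**Region expression.** For each gene the CDS and the 3'UTR are quantified
separately:

$$\mathrm{expr} = \frac{\text{reads assigned to the region}}
  {\text{effective length (kb)} \times \text{total mapped reads (millions)}}$$

The *effective length* is the count of bases with non-zero coverage, not
the annotated length: long annotated UTRs that are transcribed only in
part are normalised by the part that is actually covered. A read
overlapping a region by at least one base is assigned to it; a read
straddling the CDS–3'UTR junction therefore counts once in each region —
consistent with independent per-region coverage counting — but only once
in the gene-level total used by the expressed filter (at least 5 mapped
reads per gene, inclusive). A region with zero reads has expression 0 by
definition, so the downstream ratio is always a number for expressed genes.

**Fractional ratio.** The per-gene statistic is
$r = \mathrm{expr}_{UTR} / (\mathrm{expr}_{UTR} + \mathrm{expr}_{CDS})$,
ranging from 0 (all CDS) to 1 (all 3'UTR). Within one library the library
size cancels, and effective-length normalisation makes regions of very
different lengths comparable, which is why the ratio is computed on
normalised expression by default; a `ratio_basis = "mean_depth"` option
uses mean per-base depth over the annotated region instead. Expressed
genes with $r > 0.6$ are classed Hi 3'UTR, $r < 0.4$ Lo 3'UTR (Hi CDS);
both inequalities are strict, so a ratio exactly at a threshold is
INTERMEDIATE. Replicate concordance of the Hi set is reported as percent
identity; because "identity" admits more than one set-similarity formula,
both Jaccard (default) and overlap-over-smaller are implemented and the
choice is recorded in the run manifest.

**Peaks, valleys and pattern types.** Coverage along a 3'UTR is rarely
uniform. At single-base resolution we define
$\mathrm{FPKM}_i = d_i \times 10^9 / N$ for depth $d_i$ and library size
$N$ — each base treated as a 1-bp feature, the only length-consistent
reading of FPKM at base resolution; the threshold is a parameter so any
other convention can be matched by rescaling. A *peak* is a maximal run
longer than 150 bp in which FPKM strictly exceeds 100 in all replicates;
a *valley* is a maximal run longer than 150 bp at or below the threshold
in all replicates, inside the annotated 3'UTR. Using $\le$ for valleys
makes peak and valley base sets partition the decided bases. Genes are
then typed: **type i**, two or more peaks entirely inside the 3'UTR with
a valley between consecutive peaks; **type ii**, a single peak that
begins within 50 bp of the junction on the CDS side (or abuts it) and
runs into a short 3'UTR (at most `short_utr_max_bp`, default 1000);
**type iii**, a long 3'UTR (at least `long_utr_min_bp`, default 2000)
with at least one peak and any above-threshold CDS coverage confined to
a terminal run of at most 25% of the CDS adjacent to the junction.
The 50 bp, 1000 bp and 2000 bp cutoffs have no published values; they are
package defaults chosen to separate the archetypes cleanly on designed
profiles, and every call is reported with a rule trace so a reader can
audit which clause fired.

## Consensus semantics

"Above threshold in all replicates" can be read per base (intersect the
base sets, then length-filter) or per interval (length-filter each
replicate's runs, then intersect). The package defaults to the per-base
reading — it treats the threshold as a pointwise condition on the
replicate ensemble — and offers the interval reading behind
`peak_params(consensus = "interval")`. Under the default all-replicates
rule the two agree on continuous profiles; they differ when bases passing
in *different* replicates would chain into one run, which is only
possible with `min_replicates` below the replicate count. The test suite
compares both on random matrices.

## Coordinates

In memory, intervals are IRanges/GRanges (1-based, closed), so every
overlap, union and coverage operation uses the standard Bioconductor
machinery and format conversion is delegated to `rtracklayer` at the I/O
boundary. Everything written to disk (BED, bedGraph, peak offsets, the
junction coordinate) is BED-style 0-based half-open. The junction is
stored as the 0-based boundary between the CDS and the 3'UTR on the
transcript; the first base 3' of it belongs to the 3'UTR side, which
fixes the (otherwise arbitrary) classification of fragments that end
exactly at the junction.

Multi-transcript genes are collapsed by `transcript_policy = "union"`
(union of CDS intervals, union of 3'UTR intervals, shared bases assigned
to the CDS) because that is what region-level coverage counting over a
merged region BED measures; `"longest"` keeps the single transcript with
the largest exon span. 3'UTRs split across exons are analysed on the
spliced, transcript-oriented coordinate and projected back to genomic
intervals for output; on the minus strand all arrays are reversed first,
so "upstream/downstream" is always transcript-oriented.

## EST and element analysis

Fragments are classified UTR-only / CDS-only / junction-spanning (MIXED)
by at least `min_overlap_bp` (default 1 bp) of overlap with each region;
fragments touching neither region are excluded from the denominator and
reported separately. The junction-bin profile reports, for signed 250-bp
bins flanking the junction, the fraction of assigned fragments
overlapping each bin. Elements are assigned to peaks/valleys by their
midpoint (default), which avoids double-assignment of long elements
spanning a peak edge; an any-overlap mode exists. The permutation null
places each element uniformly (length-preserving) within the gene span
and reports $p = (1 + \#\{ \text{perm } \ge \text{obs}\}) / (1 + n_{perm})$,
deterministic given a seed. Because called peaks live inside the 3'UTR
while the span always contains CDS bases, the degenerate all-peaks span
cannot arise from package-built peak sets; the guard (p = 1 with a
warning) is retained defensively.

## What the simulator emulates — and what it does not

The generator writes single-exon genes on a synthetic chromosome, each
with designed CDS/3'UTR lengths, a true 3'UTR share $r$, and a peak
blueprint (offsets from the junction, lengths, design FPKM) over a valley
floor. Designed FPKM converts to expected depth by inverting the per-base
FPKM formula; noise is Poisson per base (counts at fixed rate) or
negative-binomial via a Gamma multiplier per 50-bp tile (overdispersion
stress test), or off. The CDS baseline FPKM is solved from $r$ so the
noise-free mean-coverage ratio equals the design exactly, including the
CDS-side mass of junction-spanning blueprints. Library sizes of roughly
0.85–1.2 × 100M reads give replicate-to-replicate variation; EST sets
default to a 0.85/0.05/0.10 UTR-only/CDS-only/mixed mixture with 200
fragments of 150–600 bp per gene; miRNA-site elements are placed inside
designed peaks and CpG/TF/H3K27ac/DNase elements in valleys, preferring
the valley immediately 5' of a peak. The default scenario ships 30 genes
across all three pattern types and flat controls, designed ratios
spanning 0.05–0.95, and four replicates.

What passing the closed loop shows is that the pipeline inverts its own
generative model at realistic depth. What it does not show: real 3'UTRs
have spliced UTRs, alternative polyadenylation, non-uniform read
sampling, mapping artefacts and annotation error, none of which the
generator emulates. Peak-boundary recovery to the base, in particular, is
a property of step-profiles with a 4:1 peak-to-threshold margin, not a
claim about real data.

## Numerical and degenerate-input choices

* Ratio with both expressions zero: undefined, returned `NA` with a
  warning and excluded from classification (the expressed filter makes
  this rare).
* Expression with zero reads: 0 regardless of effective length; reads
  with zero effective length: an impossible-state error.
* Strict inequalities everywhere the rule says "more than": run length
  `> 150` bp is `min_run_bp = 151`, FPKM `> 100`, ratio `> 0.6` / `< 0.4`;
  the expressed filter is inclusive (`>= 5`).
* Class-list ties in ratio are ordered by gene id for reproducible
  output; empty classes still produce a header-only file.
* Pipeline outputs are a pure function of inputs and configuration: one
  seed drives simulation, permutation and any other randomised step, and
  reruns are byte-identical (verified by checksum in the tests).

## Problem sizes used in the tests

The shipped suites run the full closed loop on the default 30-gene,
4-replicate scenario (~3.5 kb genes), compare the peak caller with a
brute-force oracle on 1000 random matrices up to 10 kb × 6 replicates,
and check permutation-p super-uniformity over 2000 trials at 199
permutations each — sizes chosen so the whole suite completes in a few
minutes on one core while still exercising every rule boundary.

## Known limitations

* The expressed filter is applied per gene (the read-count wording is
  ambiguous between gene and region); a per-region variant is a
  `min_reads` away but not the default.
* bedGraph input cannot recover read counts from depth alone and
  requires the companion per-region count table the generator writes.
* BED12 export assumes no 3'UTR interval falls genomically inside the
  CDS span (it warns otherwise); exotic isoform unions may not
  round-trip.
* Concordance "identity" is reported under an explicitly named metric
  rather than asserting which formula the field's reported ranges used.
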