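Package: isoutr
Title: Transcriptome-Wide Analysis of Isolated 3'UTR Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies differential expression of mRNA 3'UTRs relative to
    their cognate coding regions (CDS) from RNA-seq coverage, to detect
    isolated 3'UTRs (i3'UTRs): stably expressed 3'UTR RNA found in the
    absence, or far in excess, of its coding sequence. Parses gene
    annotation (GTF/GFF3/BED12) into per-gene CDS and 3'UTR models with a
    defined CDS-3'UTR junction; computes per-region read counts, effective
    lengths and normalized expression; classifies genes as Hi or Lo 3'UTR by
    the fractional 3'UTR/(3'UTR+CDS) ratio with replicate concordance;
    calls replicate-consensus coverage peaks and valleys inside 3'UTRs and
    types each gene's peak architecture; classifies EST/cDNA fragments as
    3'UTR-only, CDS-only or junction-spanning with a 250-bp junction-bin
    profile; aligns genomic element tracks (CpG islands, TF clusters, miRNA
    sites, H3K27ac, DNase) to peaks versus valleys with a permutation null;
    and ships a seeded synthetic-data generator with ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
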