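# cistromix

Integration of transcription factor occupancy (ChIP-seq), knockout
transcriptomes (RNA-seq/microarray) and chromatin accessibility (ATAC-seq)
for **promoter-centric transactivators** — factors that bind predominantly
within ±2 kb of transcription start sites, where their loss lowers both the
expression and the accessibility of directly bound genes, while up-regulated
genes show no local binding (indirect regulation).

The package is aimed at regulatory genomicists who have peak calls, coverage
tracks, a TSS table and per-gene expression for two conditions, and want the
promoter-centric integration analysis as tested, reusable functions rather
than one-off scripts.

## What it computes

* **Occupancy**: reads extended 200 bp in the 3′ direction; densities in
  rpm/bp; peak AUC (signal·bp) with whole-cell-extract background
  subtraction floored at zero; gene-level promoter signal
  `Σ max(AUC − AUC_bg, 0)` over peaks with summit within ±2 kb of the TSS,
  and distal signal within 1 Mb but outside the promoter.
* **Annotation**: promoter / enhancer (H3K27ac-overlapping) / other
  classification; CpG-island overlap fractions; distance-to-TSS
  distributions compared with the Epps–Singleton characteristic-function
  test.
* **Expression integration**: `<1 RPKM in all samples` filtering,
  Benjamini–Hochberg FDR, down/up/ns classes (FDR < 0.05, |log2FC| ≥ 1),
  rank-binned occupancy-vs-expression trend (median signal and median
  log2FC per bin), per-class Mann–Whitney tests, z-score heatmap matrices,
  and ±5 kb occupancy matrices/meta profiles.
* **Accessibility dynamics**: consensus ATAC peaks (≥1 bp overlap union),
  per-condition mean AUC recomputed on consensus intervals, ascending
  within-condition ranks and rank shifts, promoter accessibility change
  `log2((control+1)/(KO+1))`, and a weighted running-sum leading-edge
  enrichment score for a gene set in that ranking.
* **Motif co-occurrence**: `1 − r` (phi) distances over a binary motif-hit
  matrix, average-linkage clustering on the distance-matrix rows, and
  anchor-overlap odds ratios with Haldane correction.
* **Synthetic epigenome**: a seeded generator that plants all of the above
  structure (70% vs 40% TSS-proximal factors, occupancy-proportional
  knockout decline, binding-free up-regulation, 50% accessibility loss at
  bound promoters, two motif blocks) with full ground truth, so every stage
  is testable without downloads.

All coordinates are 0-based half-open (BED convention).

## Worked example

```r
library(cistromix)

# a seeded synthetic study: 2000 genes, 1000 peaks per factor
b <- simulate_epigenome(sim_config(seed = 1))
r <- score_recovery(b)

round(unlist(r[c("frac_tss5kb_tfa", "frac_tss5kb_tfb",
                 "cpg_fraction_tfa", "atac_es", "motif_ari")]), 4)
#> frac_tss5kb_tfa  frac_tss5kb_tfb cpg_fraction_tfa          atac_es
#>          0.7000           0.4000           0.7000           0.6750
#>       motif_ari
#>          1.0000
r$distance_es_p   # Epps-Singleton, TF-A vs TF-B distance distributions
#> [1] 4.77e-41
r$down_up_signal_p  # Mann-Whitney, promoter signal of down vs up genes
#> [1] 1.12e-57
```

Reading: the promoter-biased factor has 70% of peaks within 5 kb of a TSS
versus 40% for the contrast factor (the two distance distributions differ
at p ≈ 1e-41); planted down-regulated genes carry far more promoter signal
than up-regulated ones (p ≈ 1e-57); the set of down-regulated bound genes
is strongly enriched (ES = 0.68) among the genes losing the most promoter
accessibility in the knockout; and the two planted motif co-occurrence
blocks are recovered exactly (adjusted Rand = 1).

File-based workflows use the same functions via the CLI:

```sh
Rscript inst/cli/cistromix.R simulate --seed 1 --out-dir sim/
Rscript inst/cli/cistromix.R annotate --peaks sim/tfa_peaks.narrowPeak \
    --tss sim/tss.tsv --h3k27ac sim/h3k27ac.bed --out anno.tsv
Rscript inst/cli/cistromix.R run --config run.yaml   # full pipeline + manifest
```

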