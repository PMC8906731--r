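---
title: "Methods: promoter-centric cistrome-transcriptome-accessibility integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-centric cistrome-transcriptome-accessibility integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistromix)
```

## The analytical model

cistromix implements the integrative analysis used to characterize a
promoter-biased transactivator: a transcription factor that binds
predominantly at gene promoters, where its loss lowers both the expression
and the chromatin accessibility of its direct targets, while genes that go
*up* after knockout do so without local binding (indirect regulation). The
pipeline quantifies this picture in five stages.

**Occupancy quantification.** ChIP-seq reads are extended by 200 bp in
their 3' direction (a fragment-length surrogate) and per-base coverage is
normalized to reads per million mapped reads per base pair (rpm/bp). The
occupancy of a peak is the area under the signal curve (AUC, signal x bp)
over its interval, minus the AUC of a whole-cell-extract background track
over the same interval, floored at zero (negative occupancy is
meaningless). Gene-level promoter signal is the sum of background-subtracted
AUCs of all peaks whose summit lies within +/- 2 kb of the TSS; distal
signal sums peaks within 1 Mb but outside the promoter window.

**Peak annotation.** A peak is a *promoter* peak when its summit (or
interval midpoint when no summit is called) lies within +/- 2 kb of the
nearest TSS; a non-promoter peak overlapping an H3K27ac interval by at
least 1 bp is an *enhancer* peak; everything else is *other*. The three
categories are mutually exclusive and exhaustive. The choice of a single
representative point (summit) avoids wide peaks straddling two categories.
Distance-to-TSS distributions of two factors (within 1 Mb) are compared
with the Epps-Singleton characteristic-function test, which unlike rank
tests is consistent for discrete data and differences beyond location.

**Occupancy-expression integration.** Genes below 1 RPKM in every sample
are removed. Log2 fold changes use `log2((mean_KO + c)/(mean_control + c))`
with pseudocount c = 0.01 RPKM (stated in output metadata); differential
p-values are *inputs* to the pipeline (count-model testing is out of
scope) and are BH-adjusted. A gene is *down* when FDR < 0.05 (strict) and
log2FC <= -1 (inclusive), *up* symmetrically. Expressed genes are ranked by
promoter signal (descending, ties broken by gene id) into contiguous
near-equal bins — any remainder goes one gene each to the leading bins —
and per-bin medians of signal and log2FC trace the occupancy-expression
trend. Class-wise occupancy differences use two-sided Mann-Whitney tests.

**Accessibility dynamics.** ATAC peak sets from the two conditions are
unioned into consensus peaks (>= 1 bp overlap, transitively; mere
adjacency of half-open intervals does not merge). Per-condition mean AUC
over replicates is recomputed on the *consensus* intervals from the
condition's coverage tracks, so both conditions are measured on identical
spans. Peaks are ranked ascending by mean AUC within each condition (ties
broken by coordinate for determinism); the control-minus-knockout rank
change measures accessibility loss. Gene-level promoter accessibility is
the raw (not background-subtracted — there is no input control for ATAC)
AUC sum in the +/- 2 kb window; genes are ranked by
`log2((control + 1)/(KO + 1))` and the set of down-regulated, bound genes
is tested for leading-edge enrichment with a weighted running sum: hits
rise by `|metric|^p` normalized over all hits (p = 1 by default, 0 gives
the classic unweighted statistic), misses fall by `1/(N - |S|)`; the
enrichment score is the signed maximum deviation and the leading edge the
hits at or before the extremum. An optional seeded gene-set permutation
p-value is available; when every hit has metric exactly zero the hit
weights fall back to equal weighting.

**Motif co-occurrence.** Over a binary peaks x factors motif-hit matrix
(scanning itself is an input), the pairwise distance is `1 - r` with `r`
the Pearson correlation of hit vectors (the phi coefficient), giving
distances in [0, 2]. Factors are clustered agglomeratively with average
linkage on the Euclidean distance between rows of this distance matrix
(the direct `1 - r` dissimilarity is available behind a flag); columns are
pre-sorted lexicographically so ties resolve identically regardless of
input order. Per-factor association with anchor-factor overlap uses the
2x2 odds ratio with the Haldane correction (+0.5 to all cells) when any
cell is zero.

## Coordinate and numerical conventions

* All coordinates are 0-based, half-open (BED convention); readers and
  writers preserve this. Bases outside a track contribute zero rather than
  raising.
* Coverage is stored run-length encoded per chromosome
  (`S4Vectors::Rle`), the natural representation for sparse toy genomes of
  tens of Mb; stepwise bedGraph input is accepted directly.
* "Extended by 200 bp" is read as 3'-directional extension beyond the read
  end, not resizing to 200 bp; configurable via `extension_bp`.
* Background subtraction floors at zero. Zero-variance rows in z-score
  matrices become zero rows with a warning. The Epps-Singleton statistic
  uses t = (0.4, 0.8) scaled by the pooled semi-interquartile range,
  biased (1/n) covariances, a Moore-Penrose inverse whose rank sets the
  chi-square degrees of freedom, and the standard small-sample correction
  when both samples are below 25.

## The synthetic epigenome

`simulate_epigenome()` plants, under one master seed, the statistical
structure the analysis is designed to detect. Each artifact draws from its
own RNG stream (derived from the seed by a stable label hash), so adding
an output never perturbs existing ones.

* **Genome and genes.** Four chromosomes of 30 Mb; genes on a jittered
  grid with spacing of tens of kb (as in a gene-dense mammalian region),
  enforced >= 20 kb so that planted distal peaks (6 kb to ~spacing/2 from
  their host TSS) can never sit within 5 kb of *any* TSS. This makes the
  planted proximal fractions exactly recoverable.
* **Two factors.** TF-A places 70% of summits within +/- 1.5 kb of a TSS
  (N(0, 400 bp), truncated), TF-B 40% — the promoter-biased versus
  distally biased contrast. Peak AUCs are log-normal heights
  (meanlog 2, sdlog 0.5) times widths uniform on 200-600 bp; background
  AUC is 10% of the peak AUC plus noise.
* **Expression.** 90% of genes are expressed (log-normal RPKM, meanlog 3,
  sdlog 1); bound genes decline by `beta x (signal / max signal)` log2
  units plus N(0, 0.3) noise; the `n_direct_down` highest-occupancy bound
  genes (default 150, the scale of a strongly bound down-regulated target
  set) receive an extra 1.5-unit decline, and `n_indirect_up` unbound
  genes (default 150) rise by 1.5 units — the direct-activation /
  indirect-up asymmetry. Replicate RPKMs add 0.15 log2 units of noise.
  Per-gene p-values come from a common-variance moderated z-test
  (variances pooled across genes): with n = 2 replicates per condition a
  per-gene t-test has ~2 degrees of freedom and no power, which is
  precisely why moderated tests exist for such designs.
* **Accessibility.** Every expressed promoter is open, plus 3000 unbound
  distal sites (TF-bound promoters are a small minority of a real ATAC
  cistrome). In the knockout, peaks at TF-A-bound promoters lose 50% of
  their AUC; condition peak sets are coordinate-jittered by +/- 30 bp and
  per-replicate tracks are rectangular bumps whose mass equals the drawn
  AUC exactly, so track-based recomputation is exact.
* **Motifs.** 500 open-chromatin peaks alternate between promoter-type
  and distal-type; 7 + 5 factors follow their block's indicator with a 5%
  Bernoulli flip — block correlation ~(1 - 2 x 0.05)^2, cross-block
  negative, so the 2-cut should recover the partition exactly.

What the generator does **not** emulate: read-level sampling noise,
sequence composition and mappability, fragment-size distributions,
overlapping genes, copy-number or batch effects, and realistic peak
shapes. Passing the recovery tests therefore demonstrates correctness of
the *analysis* under the planted statistical structure, not robustness to
every artifact of real sequencing data.

## Problem sizes and acceptance-style checks

The packaged checks run the generator at the scales the analyses are
designed for: 2000 peaks per factor for the promoter-bias contrast
(observed proximal fractions within +/- 0.03 of 0.70/0.40, Epps-Singleton
p far below 1e-6); a 5000-gene, 100-bin planted trend with uniform
normalized occupancy (Spearman <= -0.9 at beta = 1, |rho| < 0.3 in >= 90%
of null runs); 500 genes per regulation class for the occupancy asymmetry
(Mann-Whitney p < 1e-6, with the up-class occupancy meta profile flat —
central bins below twice the flanks plus a 0.01 rpm floor, the floor
because an exactly zero profile would make the ratio degenerate);
consensus rank dynamics over ~4700 peaks (bound promoters drop a median
>= 5% of the ranking, unbound peaks move < 10% — exactly zero is
impossible because within-condition ranks are a permutation, so bound
peaks falling necessarily lifts the rest slightly); leading-edge
enrichment score > 0.5 for the planted down+bound set; motif adjusted
Rand = 1; and type-I error of both two-sample tests within [0.03, 0.07]
at alpha = 0.05 over 1000 null replicates.

## Known limitations

* Differential-expression testing is consumed, not performed; the
  moderated z in the generator is for simulation only.
* The enrichment stage implements a single-set leading-edge score, not a
  multi-collection GSEA with cross-set normalization and FDR.
* Peak calling, alignment, motif scanning and de novo discovery are out
  of scope; their outputs are the pipeline's inputs.
* Whether real analyses measure peak distance from summit, center or
  nearest edge varies by tool; this package fixes the summit/midpoint
  convention and exposes the window sizes as parameters.
```{r}
b <- simulate_epigenome(sim_config(seed = 1))
r <- score_recovery(b)
unlist(r[c("frac_tss5kb_tfa", "frac_tss5kb_tfb", "motif_ari")])
```
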