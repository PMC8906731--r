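Package: cistromix
Title: Cistrome-Transcriptome-Accessibility Integration for Promoter-Centric
    Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating transcription factor ChIP-seq occupancy
    with knockout transcriptomes and chromatin accessibility in a
    promoter-centric regulatory model. Provides normalized read-density and
    background-subtracted peak AUC quantification, promoter/enhancer peak
    annotation with CpG-island overlap and Epps-Singleton comparison of
    distance-to-TSS distributions, per-gene proximal and distal occupancy,
    rank-binned occupancy-versus-expression trend analysis, ATAC-seq
    consensus-peak rank-shift analysis, running-sum leading-edge enrichment
    of gene sets, motif co-occurrence clustering over open chromatin, and a
    seeded synthetic-epigenome generator with planted ground truth for
    end-to-end validation. Coordinates are 0-based half-open (BED
    convention) throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    jsonlite
Config/testthat/edition: 3
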