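# Seeded synthetic multi-assay epigenome with planted ground truth: a
# promoter-biased transactivator (TF-A) whose knockout lowers expression and
# accessibility at bound promoters, a distally-biased contrast factor (TF-B),
# and a two-block motif co-occurrence structure over open chromatin.

# independent RNG stream per artifact: stable label hash mixed with the
# master seed, so adding an output never perturbs existing ones
seed_stream <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

#' Configuration for the synthetic epigenome
#'
#' Defaults plant the study conditions the pipeline is designed around:
#' ~70% of TF-A peaks proximal to a TSS versus ~40% for TF-B, knockout
#' expression decline proportional to promoter occupancy with a strongly
#' down-regulated bound subset, indirect up-regulation without binding, and
#' halved accessibility at TF-A-bound promoters in the knockout.
#'
#' @param seed master seed; every artifact derives its own stream from it.
#' @param n_chromosomes,chrom_length genome shape (default 4 x 30 Mb, so
#'   genes are spaced tens of kb apart as in a mammalian genome).
#' @param n_genes number of genes (default 2000).
#' @param n_peaks_tf_a,promoter_fraction_tf_a TF-A peak count and planted
#'   TSS-proximal fraction (defaults 1000, 0.70).
#' @param n_peaks_tf_b,promoter_fraction_tf_b same for TF-B (1000, 0.40).
#' @param effect_beta expression decline (log2 units) per unit normalized
#'   promoter signal at bound genes (default 1).
#' @param noise_sd_log2fc SD of gene-level log2FC noise (default 0.3).
#' @param n_direct_down size of the strongly down-regulated bound subset
#'   (default 150); these get an extra `down_extra` log2-unit decline.
#' @param down_extra extra decline for the direct-down subset (default 1.5).
#' @param n_indirect_up,up_effect number and effect (+log2 units) of
#'   up-regulated genes without local binding (defaults 150, 1.5).
#' @param atac_loss_fraction knockout accessibility loss at TF-A-bound
#'   promoter ATAC peaks (default 0.5).
#' @param n_atac_distal unbound distal open-chromatin peaks (default 3000).
#' @param n_motif_peaks,n_factors_promoter,n_factors_distal,motif_noise_flip_rate
#'   motif hit-matrix shape: open-chromatin peaks, the two planted factor
#'   blocks, and the Bernoulli flip rate (defaults 500, 7, 5, 0.05).
#' @param n_replicates replicates per condition (default 2).
#' @param expressed_fraction fraction of genes expressed above 1 RPKM
#'   (default 0.9).
#' @param rep_noise_sd replicate-level log2 RPKM / log2 AUC noise SD
#'   (default 0.15).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 4, chrom_length = 3e7,
                       n_genes = 2000,
                       n_peaks_tf_a = 1000, promoter_fraction_tf_a = 0.70,
                       n_peaks_tf_b = 1000, promoter_fraction_tf_b = 0.40,
                       effect_beta = 1, noise_sd_log2fc = 0.3,
                       n_direct_down = 150, down_extra = 1.5,
                       n_indirect_up = 150, up_effect = 1.5,
                       atac_loss_fraction = 0.5, n_atac_distal = 3000,
                       n_motif_peaks = 500, n_factors_promoter = 7,
                       n_factors_distal = 5, motif_noise_flip_rate = 0.05,
                       n_replicates = 2, expressed_fraction = 0.9,
                       rep_noise_sd = 0.15) {
  cfg <- as.list(environment())
  stopifnot(cfg$promoter_fraction_tf_a >= 0, cfg$promoter_fraction_tf_a <= 1,
            cfg$promoter_fraction_tf_b >= 0, cfg$promoter_fraction_tf_b <= 1,
            cfg$atac_loss_fraction >= 0, cfg$atac_loss_fraction <= 1,
            cfg$motif_noise_flip_rate >= 0, cfg$motif_noise_flip_rate <= 0.5,
            cfg$n_genes > 0, cfg$chrom_length > 0, cfg$n_replicates >= 2)
  class(cfg) <- "sim_config"
  cfg
}

# gene models on a jittered grid so the planted proximal/distal peak
# contrast is not contaminated by accidental TSS proximity
sim_genes <- function(cfg) {
  counts <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chromosomes + 1)))
  set.seed(seed_stream(cfg$seed, "genes"))
  rows <- lapply(seq_len(cfg$n_chromosomes), function(ci) {
    nc <- counts[ci]
    if (nc == 0) return(NULL)
    spacing <- cfg$chrom_length / nc
    if (spacing < 20000)
      stop("gene spacing below 20 kb; enlarge the genome or reduce n_genes")
    tss <- floor((seq_len(nc) - 0.5) * spacing) +
      as.integer(round(stats::runif(nc, -2000, 2000)))
    data.frame(chrom = sprintf("chr%d", ci), tss = tss,
               strand = sample(c("+", "-"), nc, replace = TRUE),
               spacing = spacing, stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, rows)
  g$gene_id <- sprintf("gene_%05d", seq_len(nrow(g)))
  g[, c("gene_id", "chrom", "strand", "tss", "spacing")]
}

# TF peak set with a planted fraction of TSS-proximal summits; distal
# summits sit 6 kb to ~spacing/2-5 kb from their host TSS, never within
# 5 kb of any TSS
sim_tf_peaks <- function(cfg, genes, bound_pool, n_peaks, prom_fraction, label) {
  set.seed(seed_stream(cfg$seed, paste0("peaks_", label)))
  n_prox <- round(n_peaks * prom_fraction)
  if (n_prox > length(bound_pool))
    stop("infeasible config: more promoter peaks than available promoters (",
         label, ")")
  bound_genes <- sample(bound_pool, n_prox)
  gi <- match(bound_genes, genes$gene_id)
  prox_summit <- genes$tss[gi] +
    as.integer(round(pmax(-1500, pmin(1500, stats::rnorm(n_prox, 0, 400)))))
  n_dist <- n_peaks - n_prox
  host <- sample.int(nrow(genes), n_dist, replace = TRUE)
  off_max <- pmax(8000, genes$spacing[host] / 2 - 5000)
  off <- round(stats::runif(n_dist, 6000, off_max)) *
    sample(c(-1L, 1L), n_dist, replace = TRUE)
  dist_summit <- as.integer(genes$tss[host] + off)
  summit <- c(prox_summit, dist_summit)
  chrom <- c(genes$chrom[gi], genes$chrom[host])
  n <- length(summit)
  w <- as.integer(round(stats::runif(n, 200, 600)))
  height <- stats::rlnorm(n, meanlog = 2, sdlog = 0.5)
  auc <- height * w
  bg <- pmax(0, 0.1 * auc * (1 + stats::rnorm(n, 0, 0.2)))
  data.frame(chrom = chrom, start = summit - w %/% 2L,
             end = summit - w %/% 2L + w,
             name = sprintf("%s_peak_%04d", label, seq_len(n)),
             summit = summit, auc = auc, background_auc = bg,
             planted_class = rep(c("proximal", "distal"), c(n_prox, n_dist)),
             bound_gene = c(bound_genes, rep(NA_character_, n_dist)),
             stringsAsFactors = FALSE)
}

#' Generate the synthetic multi-assay bundle
#'
#' Produces gene models, TF-A/TF-B peak sets with planted summits and AUCs,
#' control/knockout expression with replicate RPKMs and p-values, CpG
#' islands and H3K27ac intervals, per-condition-and-replicate ATAC peaks and
#' coverage tracks, ChIP and background coverage tracks, a two-block motif
#' hit matrix over open chromatin, and the ground truth behind all of it.
#' With the same config (including seed) the bundle is reproducible
#' byte-for-byte.
#'
#' @param cfg a [sim_config()].
#' @param out_dir if non-`NULL`, the bundle is also written there in standard
#'   formats (TSV, narrowPeak, bedGraph, BED) plus a `manifest.yaml`.
#' @param tracks build coverage tracks (ChIP, background, histone, ATAC)?
#'   Defaults to `TRUE` when `out_dir` is given, else `FALSE`; the
#'   occupancy-math columns are always present regardless.
#' @return list with elements `genes`, `expression`, `peaks_tfa`,
#'   `peaks_tfb`, `cpg`, `h3k27ac`, `atac`, `motif`, `tracks`, `truth`,
#'   `config`.
#' @export
simulate_epigenome <- function(cfg = sim_config(), out_dir = NULL,
                               tracks = !is.null(out_dir)) {
  genes <- sim_genes(cfg)

  # expression baseline and expressed set
  set.seed(seed_stream(cfg$seed, "expression_baseline"))
  n <- nrow(genes)
  expressed <- stats::runif(n) < cfg$expressed_fraction
  rpkm0 <- ifelse(expressed,
                  stats::rlnorm(n, meanlog = 3, sdlog = 1),
                  stats::runif(n, 0, 0.8))
  rpkm0 <- pmax(rpkm0, ifelse(expressed, 1.05, 0)) # expressed means >= 1 RPKM

  pool <- genes$gene_id[expressed]
  peaks_tfa <- sim_tf_peaks(cfg, genes, pool, cfg$n_peaks_tf_a,
                            cfg$promoter_fraction_tf_a, "tfa")
  peaks_tfb <- sim_tf_peaks(cfg, genes, pool, cfg$n_peaks_tf_b,
                            cfg$promoter_fraction_tf_b, "tfb")

  # planted expression effects
  set.seed(seed_stream(cfg$seed, "expression_effects"))
  prox <- peaks_tfa[peaks_tfa$planted_class == "proximal", ]
  sig_true <- numeric(n)
  gi <- match(prox$bound_gene, genes$gene_id)
  sig_true[gi] <- background_subtracted_auc(prox$auc, prox$background_auc)
  bound <- sig_true > 0
  log2fc_true <- numeric(n)
  if (any(bound))
    log2fc_true[bound] <- -cfg$effect_beta * sig_true[bound] / max(sig_true)
  status <- rep("null", n)
  dd <- order(-sig_true)[seq_len(min(cfg$n_direct_down, sum(bound)))]
  status[dd] <- "direct_down"
  log2fc_true[dd] <- log2fc_true[dd] - cfg$down_extra
  up_pool <- which(expressed & !bound & status == "null")
  iu <- sample(up_pool, min(cfg$n_indirect_up, length(up_pool)))
  status[iu] <- "indirect_up"
  log2fc_true[iu] <- cfg$up_effect
  log2fc_noisy <- log2fc_true + stats::rnorm(n, 0, cfg$noise_sd_log2fc)

  # replicate RPKMs and a per-gene two-sample test on log2 RPKM
  set.seed(seed_stream(cfg$seed, "expression_replicates"))
  nr <- cfg$n_replicates
  ctl <- matrix(rpkm0, n, nr) * 2^stats::rnorm(n * nr, 0, cfg$rep_noise_sd)
  ko <- matrix(rpkm0 * 2^log2fc_noisy, n, nr) *
    2^stats::rnorm(n * nr, 0, cfg$rep_noise_sd)
  expression <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (r in seq_len(nr)) expression[[sprintf("control_%d", r)]] <- ctl[, r]
  for (r in seq_len(nr)) expression[[sprintf("ko_%d", r)]] <- ko[, r]
  expression$p_value <- moderated_p(log2(ctl + 0.01), log2(ko + 0.01))

  # CpG islands at TF-A-bound promoters (plus a sprinkle of others) and
  # H3K27ac at expressed promoters and at a share of distal peaks
  set.seed(seed_stream(cfg$seed, "annotation_intervals"))
  cpg_genes <- unique(c(prox$bound_gene,
                        sample(genes$gene_id, round(0.05 * n))))
  ci <- match(cpg_genes, genes$gene_id)
  cpg <- data.frame(chrom = genes$chrom[ci], start = genes$tss[ci] - 2000L,
                    end = genes$tss[ci] + 2000L, stringsAsFactors = FALSE)
  k27_prom <- data.frame(chrom = genes$chrom[expressed],
                         start = genes$tss[expressed] - 1500L,
                         end = genes$tss[expressed] + 1500L,
                         stringsAsFactors = FALSE)
  dist_pk <- rbind(peaks_tfa[peaks_tfa$planted_class == "distal",
                             c("chrom", "start", "end")],
                   peaks_tfb[peaks_tfb$planted_class == "distal",
                             c("chrom", "start", "end")])
  is_enh <- stats::runif(nrow(dist_pk)) < 0.6
  k27_enh <- data.frame(chrom = dist_pk$chrom[is_enh],
                        start = dist_pk$start[is_enh] - 500L,
                        end = dist_pk$end[is_enh] + 500L,
                        stringsAsFactors = FALSE)
  h3k27ac <- rbind(k27_prom, k27_enh)

  atac <- sim_atac(cfg, genes, expressed, bound, tracks)
  motif <- sim_motif(cfg)

  trk <- NULL
  if (tracks) {
    trk <- list(
      tfa = rect_track(peaks_tfa, peaks_tfa$auc, cfg),
      wce = rect_track(peaks_tfa, peaks_tfa$background_auc, cfg),
      h3k27ac = interval_track(h3k27ac, 2.0, cfg),
      h3k4me1 = interval_track(k27_enh, 1.5, cfg)
    )
  }

  truth <- list(
    genes = data.frame(gene_id = genes$gene_id, expressed = expressed,
                       bound_tfa = bound, promoter_signal_true = sig_true,
                       log2fc_true = log2fc_true, status = status,
                       stringsAsFactors = FALSE),
    peaks_tfa = peaks_tfa[, c("name", "planted_class", "bound_gene")],
    peaks_tfb = peaks_tfb[, c("name", "planted_class", "bound_gene")],
    atac = atac$truth,
    motif = motif$truth
  )
  bundle <- list(genes = genes[, c("gene_id", "chrom", "strand", "tss")],
                 expression = expression,
                 peaks_tfa = peaks_tfa[, c("chrom", "start", "end", "name",
                                           "summit", "auc", "background_auc")],
                 peaks_tfb = peaks_tfb[, c("chrom", "start", "end", "name",
                                           "summit", "auc", "background_auc")],
                 cpg = cpg, h3k27ac = h3k27ac,
                 atac = atac[c("peaks_control", "peaks_ko",
                               "tracks_control", "tracks_ko")],
                 motif = motif[c("hits", "anchors")],
                 tracks = trk, truth = truth, config = cfg)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# moderated two-sample test across rows of two matrices: per-gene variances
# are pooled into a common (gene-shared) variance before the z-statistic,
# the usual remedy for n = 2 replicates per condition where a per-gene
# t-test has ~2 degrees of freedom and no power
moderated_p <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  se <- sqrt(mean(va) / na + mean(vb) / nb)
  z <- (ma - mb) / se
  p <- 2 * stats::pnorm(-abs(z))
  p[!is.finite(p)] <- 1
  pmin(pmax(p, 0), 1)
}

sim_atac <- function(cfg, genes, expressed, bound, tracks) {
  set.seed(seed_stream(cfg$seed, "atac"))
  # promoter open chromatin at every expressed gene + unbound distal sites
  pi <- which(expressed)
  n_prom <- length(pi)
  host <- sample.int(nrow(genes), cfg$n_atac_distal, replace = TRUE)
  off_max <- pmax(8000, genes$spacing[host] / 2 - 5000)
  off <- round(stats::runif(cfg$n_atac_distal, 6000, off_max)) *
    sample(c(-1L, 1L), cfg$n_atac_distal, replace = TRUE)
  summit <- c(genes$tss[pi] + as.integer(round(stats::rnorm(n_prom, 0, 100))),
              as.integer(genes$tss[host] + off))
  chrom <- c(genes$chrom[pi], genes$chrom[host])
  n <- length(summit)
  w <- as.integer(round(stats::runif(n, 400, 800)))
  start <- summit - w %/% 2L; end <- start + w
  auc_true <- stats::rlnorm(n, meanlog = 2, sdlog = 0.5) * w
  bound_peak <- c(bound[pi], rep(FALSE, cfg$n_atac_distal))
  auc_ko_true <- auc_true * ifelse(bound_peak, 1 - cfg$atac_loss_fraction, 1)
  nr <- cfg$n_replicates
  rep_auc <- function(mu) matrix(mu, n, nr) * 2^stats::rnorm(n * nr, 0, 0.1)
  auc_ctl_rep <- rep_auc(auc_true)
  auc_ko_rep <- rep_auc(auc_ko_true)
  jitter_cond <- function(tag) {
    j <- as.integer(round(stats::runif(n, -30, 30)))
    data.frame(chrom = chrom, start = start + j, end = end + j,
               name = sprintf("atac_%s_%05d", tag, seq_len(n)),
               summit = summit + j, auc = 0, background_auc = 0,
               stringsAsFactors = FALSE)
  }
  peaks_control <- jitter_cond("ctl")
  peaks_ko <- jitter_cond("ko")
  peaks_control$auc <- rowMeans(auc_ctl_rep)
  peaks_ko$auc <- rowMeans(auc_ko_rep)
  tr_ctl <- tr_ko <- NULL
  if (tracks) {
    tr_ctl <- lapply(seq_len(nr), function(r)
      rect_track(peaks_control, auc_ctl_rep[, r], cfg))
    tr_ko <- lapply(seq_len(nr), function(r)
      rect_track(peaks_ko, auc_ko_rep[, r], cfg))
  }
  list(peaks_control = peaks_control, peaks_ko = peaks_ko,
       tracks_control = tr_ctl, tracks_ko = tr_ko,
       truth = data.frame(name_control = peaks_control$name,
                          name_ko = peaks_ko$name, chrom = chrom,
                          summit = summit, bound_tfa = bound_peak,
                          promoter_peak = c(rep(TRUE, n_prom),
                                            rep(FALSE, cfg$n_atac_distal)),
                          gene_id = c(genes$gene_id[pi],
                                      rep(NA_character_, cfg$n_atac_distal)),
                          auc_control_true = auc_true,
                          auc_ko_true = auc_ko_true,
                          stringsAsFactors = FALSE))
}

sim_motif <- function(cfg) {
  set.seed(seed_stream(cfg$seed, "motif"))
  np <- cfg$n_motif_peaks
  peak_type <- rep(c("promoter", "distal"), length.out = np)
  factors <- c(sprintf("FacP%02d", seq_len(cfg$n_factors_promoter)),
               sprintf("FacD%02d", seq_len(cfg$n_factors_distal)))
  block <- rep(c("promoter", "distal"),
               c(cfg$n_factors_promoter, cfg$n_factors_distal))
  base <- outer(peak_type == "promoter", block == "promoter",
                function(p, b) p == b) * 1L
  flip <- matrix(stats::runif(np * length(factors)) < cfg$motif_noise_flip_rate,
                 np, length(factors))
  hits <- abs(base - flip * 1L)
  dimnames(hits) <- list(sprintf("oc_peak_%04d", seq_len(np)), factors)
  anchors <- data.frame(anchor_tfa = as.integer(peak_type == "promoter"),
                        anchor_tfb = as.integer(peak_type == "distal"))
  rownames(anchors) <- rownames(hits)
  list(hits = hits, anchors = anchors,
       truth = list(factor_block = stats::setNames(block, factors),
                    peak_type = stats::setNames(peak_type, rownames(hits))))
}

# rectangular-bump track: each peak contributes auc/width over its
# interval; overlapping rectangles add, so per-peak AUC mass is preserved
rect_track <- function(peaks, auc, cfg) {
  height <- auc / (peaks$end - peaks$start)
  lens <- stats::setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                          sprintf("chr%d", seq_len(cfg$n_chromosomes)))
  cov <- lapply(names(lens), function(cn) {
    i <- which(peaks$chrom == cn)
    if (!length(i)) return(S4Vectors::Rle(0, lens[[cn]]))
    ir <- IRanges::IRanges(start = pmax(peaks$start[i], 0L) + 1L,
                           end = pmin(peaks$end[i], lens[[cn]]))
    IRanges::coverage(ir, weight = height[i], width = lens[[cn]])
  })
  names(cov) <- names(lens)
  signal_track(cov, total_mapped = 2e7)
}

interval_track <- function(intervals, height, cfg) {
  if (!nrow(intervals)) {
    lens <- stats::setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                            sprintf("chr%d", seq_len(cfg$n_chromosomes)))
    return(track_from_segments(
      data.frame(chrom = character(), start = integer(), end = integer(),
                 value = numeric()), chrom_lengths = lens))
  }
  seg <- data.frame(chrom = intervals$chrom, start = pmax(intervals$start, 0L),
                    end = intervals$end, value = height,
                    stringsAsFactors = FALSE)
  seg <- seg[order(seg$chrom, seg$start), ]
  # collapse overlapping intervals to a flat plateau
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    seg$chrom, IRanges::IRanges(seg$start + 1L, seg$end)))
  gr <- GenomicRanges::sort(gr)
  seg <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr), value = height,
                    stringsAsFactors = FALSE)
  lens <- stats::setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                          sprintf("chr%d", seq_len(cfg$n_chromosomes)))
  track_from_segments(seg, chrom_lengths = lens)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_tss_table(bundle$genes, p("tss.tsv"))
  write_peaks(bundle$peaks_tfa, p("tfa_peaks.narrowPeak"))
  write_peaks(bundle$peaks_tfb, p("tfb_peaks.narrowPeak"))
  utils::write.table(bundle$cpg, p("cpg.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(bundle$h3k27ac, p("h3k27ac.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(bundle$expression, p("expression.tsv"))
  write_peaks(bundle$atac$peaks_control, p("atac_control_peaks.narrowPeak"))
  write_peaks(bundle$atac$peaks_ko, p("atac_ko_peaks.narrowPeak"))
  if (!is.null(bundle$tracks)) {
    write_bedgraph(bundle$tracks$tfa, p("tfa.bedGraph"))
    write_bedgraph(bundle$tracks$wce, p("wce.bedGraph"))
    write_bedgraph(bundle$tracks$h3k27ac, p("h3k27ac.bedGraph"))
    write_bedgraph(bundle$tracks$h3k4me1, p("h3k4me1.bedGraph"))
    for (r in seq_along(bundle$atac$tracks_control)) {
      write_bedgraph(bundle$atac$tracks_control[[r]],
                     p(sprintf("atac_control_rep%d.bedGraph", r)))
      write_bedgraph(bundle$atac$tracks_ko[[r]],
                     p(sprintf("atac_ko_rep%d.bedGraph", r)))
    }
  }
  hits_df <- data.frame(peak_id = rownames(bundle$motif$hits),
                        bundle$motif$anchors, bundle$motif$hits,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(hits_df, p("motif_hits.tsv"))
  write_tsv(bundle$truth$genes, p("truth", "genes.tsv"))
  write_tsv(bundle$truth$peaks_tfa, p("truth", "peaks_tfa.tsv"))
  write_tsv(bundle$truth$peaks_tfb, p("truth", "peaks_tfb.tsv"))
  write_tsv(bundle$truth$atac, p("truth", "atac.tsv"))
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.yaml"))
  manifest <- list(
    generator = "cistromix::simulate_epigenome",
    config = unclass(bundle$config),
    files = files
  )
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(out_dir)
}
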