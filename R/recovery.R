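# Runs the pipeline stages over a synthetic bundle and scores how well each
# planted quantity is recovered.

#' Score pipeline recovery of planted ground truth
#'
#' Runs annotation, expression integration, accessibility dynamics and motif
#' clustering on a synthetic bundle and compares the results with the
#' bundle's ground truth.
#'
#' @param bundle result of [simulate_epigenome()].
#' @param n_bins bins for the occupancy-expression trend (default 100).
#' @param enrichment_set_size size of the down+bound query set for the
#'   leading-edge enrichment (default: all planted direct-down genes).
#' @return named list of recovery metrics; see Details.
#' @details Reported metrics: `frac_tss5kb_tfa` / `frac_tss5kb_tfb`
#'   (fraction of peaks within 5 kb of a TSS) with the planted values and
#'   errors; `distance_es_p` (Epps-Singleton p comparing the two factors'
#'   distance distributions); `trend_spearman` (Spearman correlation of bin
#'   median occupancy vs bin median log2FC); `down_up_signal_p`
#'   (Mann-Whitney p, promoter signal of planted direct-down vs indirect-up
#'   genes); `up_meta_central`, `up_meta_flank`, `down_meta_central`
#'   (occupancy meta-profile summaries around up/down TSSs);
#'   `bound_rank_drop_median`, `unbound_rank_change_median` (consensus ATAC
#'   rank shifts); `atac_es` (leading-edge enrichment of down+bound genes in
#'   the accessibility-loss ranking); `motif_ari` (adjusted Rand of the
#'   2-cut motif clustering vs the planted blocks); `cpg_fraction_tfa`.
#' @export
score_recovery <- function(bundle, n_bins = 100, enrichment_set_size = NULL) {
  genes <- bundle$genes
  truth <- bundle$truth
  if (!identical(truth$genes$gene_id, genes$gene_id))
    stop("bundle truth and gene universe do not match")
  out <- list()

  # --- promoter-bias recovery and distance distributions
  d_a <- distances_to_nearest_tss(bundle$peaks_tfa, genes)
  d_b <- distances_to_nearest_tss(bundle$peaks_tfb, genes)
  out$frac_tss5kb_tfa <- mean(d_a <= 5000)
  out$frac_tss5kb_tfb <- mean(d_b <= 5000)
  out$frac_tss5kb_tfa_planted <- bundle$config$promoter_fraction_tf_a
  out$frac_tss5kb_tfb_planted <- bundle$config$promoter_fraction_tf_b
  out$frac_error_tfa <- abs(out$frac_tss5kb_tfa - out$frac_tss5kb_tfa_planted)
  out$frac_error_tfb <- abs(out$frac_tss5kb_tfb - out$frac_tss5kb_tfb_planted)
  es <- epps_singleton_test(d_a, d_b)
  out$distance_es_stat <- es$statistic
  out$distance_es_p <- es$p_value
  out$cpg_fraction_tfa <- cpg_overlap_fraction(bundle$peaks_tfa, bundle$cpg)

  # --- expression integration
  expr <- filter_expressed(bundle$expression)
  nr <- bundle$config$n_replicates
  ctl_cols <- sprintf("control_%d", seq_len(nr))
  ko_cols <- sprintf("ko_%d", seq_len(nr))
  expr$log2fc <- expression_log2fc(expr, ko_cols, ctl_cols)
  expr$fdr <- bh_fdr(expr$p_value)
  expr$reg_class <- classify_regulation(expr$log2fc, expr$fdr)
  gx <- genes[match(expr$gene_id, genes$gene_id), ]
  expr$promoter_signal <- gene_promoter_signal(gx, bundle$peaks_tfa)
  trend <- binned_occupancy_trend(expr$gene_id, expr$promoter_signal,
                                  expr$log2fc, n_bins = min(n_bins, nrow(expr)))
  out$trend_spearman <- stats::cor(trend$median_signal, trend$median_log2fc,
                                   method = "spearman")

  status <- truth$genes$status[match(expr$gene_id, truth$genes$gene_id)]
  dn <- expr$promoter_signal[status == "direct_down"]
  up <- expr$promoter_signal[status == "indirect_up"]
  if (length(dn) && length(up)) {
    wt <- suppressWarnings(stats::wilcox.test(dn, up))
    out$down_up_signal_p <- wt$p.value
    out$down_up_signal_gap <- mean(dn) - mean(up)
  }

  # --- occupancy meta profiles around up/down TSSs (needs the ChIP track)
  if (!is.null(bundle$tracks)) {
    meta_of <- function(ids) {
      gi <- genes[genes$gene_id %in% ids, ]
      om <- occupancy_matrix(data.frame(chrom = gi$chrom, pos = gi$tss),
                             bundle$tracks$tfa, flank = 5000, n_cols = 50)
      om$meta
    }
    meta_up <- meta_of(expr$gene_id[status == "indirect_up"])
    meta_dn <- meta_of(expr$gene_id[status == "direct_down"])
    central <- 24:27; flank_cols <- c(1:5, 46:50)
    out$up_meta_central <- mean(meta_up[central])
    out$up_meta_flank <- mean(meta_up[flank_cols])
    out$down_meta_central <- mean(meta_dn[central])
    out$down_meta_flank <- mean(meta_dn[flank_cols])
  }

  # --- accessibility rank dynamics and leading-edge enrichment
  cons <- merge_consensus(bundle$atac$peaks_control, bundle$atac$peaks_ko,
                          tracks_control = bundle$atac$tracks_control,
                          tracks_ko = bundle$atac$tracks_ko,
                          tf_peaks = bundle$peaks_tfa)
  cons <- rank_peaks(cons)
  # map consensus peaks back to planted ATAC peaks via control summit
  at <- truth$atac
  pc <- bundle$atac$peaks_control
  idx <- assign_first(cons, pc)
  bound_flag <- at$bound_tfa[idx]
  out$n_consensus <- nrow(cons)
  out$bound_rank_drop_median <-
    stats::median(cons$rank_change[which(bound_flag)])
  out$unbound_rank_change_median <-
    stats::median(cons$rank_change[which(!bound_flag)])

  atac_ctl <- promoter_atac_signal(gx, bundle$atac$peaks_control)
  atac_ko <- promoter_atac_signal(gx, bundle$atac$peaks_ko)
  metric <- atac_rank_metric(atac_ctl, atac_ko)
  o <- order(-metric, expr$gene_id)
  query <- truth$genes$gene_id[truth$genes$status == "direct_down"]
  query <- intersect(query, expr$gene_id)
  if (!is.null(enrichment_set_size))
    query <- utils::head(query, enrichment_set_size)
  er <- enrichment_score(expr$gene_id[o], metric[o], query)
  out$atac_es <- er$es
  out$atac_leading_edge_n <- length(er$leading_edge)

  # --- motif block recovery
  dmat <- cooccurrence_distance(bundle$motif$hits)
  cl <- cluster_motifs(dmat, n_clusters = 2)
  planted <- bundle$truth$motif$factor_block[names(cl$labels)]
  out$motif_ari <- mclust::adjustedRandIndex(cl$labels, planted)
  assoc <- anchor_association(bundle$motif$hits,
                              bundle$motif$anchors$anchor_tfa)
  blocks <- bundle$truth$motif$factor_block[assoc$factor]
  out$promoter_factor_min_or <- min(assoc$odds_ratio[blocks == "promoter"])
  out$distal_factor_max_or <- max(assoc$odds_ratio[blocks == "distal"])
  out
}

# index of the planted control peak whose summit lies in each consensus peak
assign_first <- function(cons, peaks) {
  q <- GenomicRanges::GRanges(cons$chrom,
                              IRanges::IRanges(cons$start + 1L, cons$end))
  s <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$summit + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(q, s, select = "first")
  hit
}

#' Planted occupancy-expression trend simulation
#'
#' Draws per-gene normalized occupancy uniformly on `[0, 1]` and plants
#' `log2fc = -beta * signal + noise`, then recovers the trend with
#' [binned_occupancy_trend()] and returns the Spearman correlation between
#' bin median signal and bin median log2FC. A direct parameter-recovery
#' check of the binned trend estimator.
#'
#' @param n_genes number of genes (default 5000).
#' @param beta planted effect size (default 1).
#' @param noise_sd log2FC noise SD (default 0.3).
#' @param n_bins number of bins (default 100).
#' @param seed RNG seed.
#' @return list with `spearman` and the `trend` data.frame.
#' @export
planted_trend_sim <- function(n_genes = 5000, beta = 1, noise_sd = 0.3,
                              n_bins = 100, seed = 1) {
  set.seed(seed)
  signal <- stats::runif(n_genes)
  log2fc <- -beta * signal + stats::rnorm(n_genes, 0, noise_sd)
  ids <- sprintf("g%05d", seq_len(n_genes))
  trend <- binned_occupancy_trend(ids, signal, log2fc, n_bins)
  list(spearman = stats::cor(trend$median_signal, trend$median_log2fc,
                             method = "spearman"),
       trend = trend)
}
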