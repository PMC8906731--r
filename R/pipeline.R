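# End-to-end orchestration: annotate -> integrate -> atac-rank -> enrich ->
# motif-cluster, with a self-describing manifest.

pipeline_defaults <- function() {
  list(promoter_window = 2000, distance_limit = 1e6, far_limit = 1e6,
       n_bins = 1000, min_rpkm = 1, fc_threshold = 1, fdr_threshold = 0.05,
       pseudocount_rpkm = 0.01, atac_pseudocount = 1, weight_exponent = 1,
       motif_cut = 2, seed = 1, verbose = TRUE)
}

#' Load a pipeline run configuration
#'
#' Reads a YAML file of input paths and parameter overrides, fills in the
#' documented defaults, and checks that every referenced path exists.
#' Recognized path keys: `tss`, `peaks_tf`, `peaks_tf_distal`, `h3k27ac`,
#' `cpg`, `expression`, `atac_peaks_control`, `atac_peaks_ko`,
#' `motif_hits`, and `out_dir`.
#'
#' @param path YAML config file.
#' @param overrides named list overriding config values (CLI flags beat the
#'   file).
#' @return validated config list.
#' @export
run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  defaults <- pipeline_defaults()
  missing <- setdiff(names(defaults), names(cfg))
  cfg[missing] <- defaults[missing]
  path_keys <- intersect(c("tss", "peaks_tf", "peaks_tf_distal", "h3k27ac",
                           "cpg", "expression", "atac_peaks_control",
                           "atac_peaks_ko", "motif_hits"), names(cfg))
  for (k in path_keys)
    if (!file.exists(cfg[[k]])) stop("config path for '", k, "' not found: ",
                                     cfg[[k]])
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  cfg
}

log_line <- function(cfg, con, ...) {
  msg <- paste0(...)
  if (isTRUE(cfg$verbose)) message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full integration analysis
#'
#' Executes the stages in order — peak annotation, expression integration,
#' ATAC rank analysis, leading-edge enrichment, motif clustering — writing
#' each stage's tables plus a summary and a machine-readable
#' `manifest.yaml` into `out_dir`. Stages whose inputs are not configured
#' are skipped and recorded as such. A failing stage aborts with the stage
#' named and leaves a `FAILED` marker next to the partial outputs.
#'
#' @param cfg config list from [run_config()], or a named list with the same
#'   keys.
#' @return (invisibly) list of in-memory stage results.
#' @export
run_full_analysis <- function(cfg) {
  defaults <- pipeline_defaults()
  missing <- setdiff(names(defaults), names(cfg))
  cfg[missing] <- defaults[missing]
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  res <- list()
  summary <- list()
  stage <- "setup"
  tryCatch({
    set.seed(cfg$seed)
    genes <- read_tss_table(cfg$tss)
    peaks <- read_peaks(cfg$peaks_tf)
    log_line(cfg, logf, "setup: ", nrow(genes), " genes, ", nrow(peaks),
             " anchor TF peaks")

    stage <- "annotate"
    h3k <- if (!is.null(cfg$h3k27ac)) read_bed(cfg$h3k27ac) else NULL
    cpg <- if (!is.null(cfg$cpg)) read_bed(cfg$cpg) else NULL
    anno <- annotate_peaks(peaks, genes, h3k, cpg,
                           promoter_window = cfg$promoter_window,
                           distance_limit = cfg$distance_limit)
    write_tsv(anno, file.path(cfg$out_dir, "peak_annotation.tsv"))
    summary$category_counts <- as.list(table(anno$category))
    summary$cpg_fraction <- if (!is.null(cpg)) cpg_overlap_fraction(peaks, cpg) else NA
    res$annotation <- anno
    log_line(cfg, logf, "annotate: in ", nrow(peaks), " peaks, out ",
             nrow(anno), " annotations")

    stage <- "integrate"
    res <- c(res, stage_integrate(cfg, genes, peaks, summary, logf))
    summary <- res$summary; res$summary <- NULL

    stage <- "atac-rank"
    if (!is.null(cfg$atac_peaks_control) && !is.null(cfg$atac_peaks_ko)) {
      atac <- stage_atac(cfg, genes, peaks, res$expression, logf)
      res <- c(res, atac)
      summary$atac_es <- atac$enrichment$es
      summary$n_consensus_peaks <- nrow(atac$consensus)
    } else {
      log_line(cfg, logf, "atac-rank: skipped (no ATAC inputs)")
    }

    stage <- "motif-cluster"
    if (!is.null(cfg$motif_hits)) {
      mh <- read_motif_hits(cfg$motif_hits)
      dmat <- cooccurrence_distance(mh$hits)
      cl <- cluster_motifs(dmat, n_clusters = cfg$motif_cut)
      lab <- data.frame(factor = names(cl$labels), cluster = cl$labels)
      write_tsv(lab, file.path(cfg$out_dir, "motif_clusters.tsv"))
      write_tsv(cl$merge, file.path(cfg$out_dir, "motif_merge_tree.tsv"))
      if (ncol(mh$anchors) > 0) {
        assoc <- anchor_association(mh$hits, mh$anchors[[1]])
        write_tsv(assoc, file.path(cfg$out_dir, "motif_anchor_association.tsv"))
        res$anchor_association <- assoc
      }
      res$motif_clusters <- lab
      summary$motif_cluster_sizes <- as.list(table(cl$labels))
      log_line(cfg, logf, "motif-cluster: ", ncol(mh$hits), " factors -> ",
               cfg$motif_cut, " clusters")
    } else {
      log_line(cfg, logf, "motif-cluster: skipped (no hit matrix)")
    }

    stage <- "report"
    manifest <- list(tool = "cistromix", schema_version = "1",
                     parameters = cfg[setdiff(names(cfg),
                                              c("verbose", "out_dir"))],
                     summary = summary)
    yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
    log_line(cfg, logf, "report: manifest written")
  }, error = function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}

stage_integrate <- function(cfg, genes, peaks, summary, logf) {
  expr <- read_expression_table(cfg$expression)
  rpkm_cols <- setdiff(names(expr), c("gene_id", "p_value"))
  ctl_cols <- grep("^control", rpkm_cols, value = TRUE)
  ko_cols <- grep("^ko", rpkm_cols, value = TRUE)
  if (!length(ctl_cols) || !length(ko_cols))
    stop("expression table needs control_* and ko_* RPKM columns")
  n_in <- nrow(expr)
  expr <- filter_expressed(expr, min_rpkm = cfg$min_rpkm, rpkm_cols = rpkm_cols)
  expr$log2fc <- expression_log2fc(expr, ko_cols, ctl_cols,
                                   pseudocount = cfg$pseudocount_rpkm)
  if (is.null(expr$p_value))
    stop("expression table needs a p_value column (differential testing is an input)")
  expr$fdr <- bh_fdr(expr$p_value)
  expr$reg_class <- classify_regulation(expr$log2fc, expr$fdr,
                                        fc_threshold = cfg$fc_threshold,
                                        fdr_threshold = cfg$fdr_threshold)
  gx <- genes[match(expr$gene_id, genes$gene_id), ]
  expr$promoter_signal <- gene_promoter_signal(gx, peaks,
                                               window = cfg$promoter_window)
  if (!is.null(cfg$peaks_tf_distal)) {
    dp <- read_peaks(cfg$peaks_tf_distal)
    expr$distal_signal <- gene_distal_signal(gx, dp, far_limit = cfg$far_limit,
                                             promoter_window = cfg$promoter_window)
  }
  write_tsv(expr, file.path(cfg$out_dir, "gene_occupancy_expression.tsv"))
  trend <- binned_occupancy_trend(expr$gene_id, expr$promoter_signal,
                                  expr$log2fc,
                                  n_bins = min(cfg$n_bins, nrow(expr)))
  write_tsv(trend, file.path(cfg$out_dir, "occupancy_trend.tsv"))
  cls <- signal_by_class_test(expr$promoter_signal, expr$reg_class)
  write_tsv(cls, file.path(cfg$out_dir, "signal_by_class.tsv"))
  summary$class_counts <- as.list(table(expr$reg_class))
  summary$n_expressed <- nrow(expr)
  summary$trend_spearman <- stats::cor(trend$median_signal,
                                       trend$median_log2fc,
                                       method = "spearman")
  log_line(cfg, logf, "integrate: in ", n_in, " genes, out ", nrow(expr),
           " expressed")
  list(expression = expr, trend = trend, class_tests = cls, summary = summary)
}

stage_atac <- function(cfg, genes, peaks, expr, logf) {
  pc <- read_peaks(cfg$atac_peaks_control)
  pk <- read_peaks(cfg$atac_peaks_ko)
  read_track_list <- function(paths) {
    if (is.null(paths)) return(NULL)
    lapply(paths, read_bedgraph)
  }
  cons <- merge_consensus(pc, pk,
                          tracks_control = read_track_list(cfg$atac_tracks_control),
                          tracks_ko = read_track_list(cfg$atac_tracks_ko),
                          tf_peaks = peaks)
  cons <- rank_peaks(cons)
  write_tsv(cons, file.path(cfg$out_dir, "atac_consensus_ranks.tsv"))
  write_tsv(cons[, c("rank_control", "rank_ko", "anchor_tf_auc")],
            file.path(cfg$out_dir, "atac_rank_scatter.tsv"))
  gx <- genes[match(expr$gene_id, genes$gene_id), ]
  ctl_sig <- promoter_atac_signal(gx, pc, window = cfg$promoter_window)
  ko_sig <- promoter_atac_signal(gx, pk, window = cfg$promoter_window)
  metric <- atac_rank_metric(ctl_sig, ko_sig,
                             pseudocount = cfg$atac_pseudocount)
  o <- order(-metric, expr$gene_id)
  query <- expr$gene_id[expr$reg_class == "down" & expr$promoter_signal > 0]
  enr <- enrichment_score(expr$gene_id[o], metric[o], query,
                          weight_exponent = cfg$weight_exponent)
  running <- data.frame(rank = seq_along(o), gene_id = expr$gene_id[o],
                        metric = metric[o], running_sum = enr$running_sum)
  write_tsv(running, file.path(cfg$out_dir, "atac_enrichment_running_sum.tsv"))
  writeLines(enr$leading_edge,
             file.path(cfg$out_dir, "atac_leading_edge.txt"))
  log_line(cfg, logf, "atac-rank: ", nrow(cons), " consensus peaks; es = ",
           signif(enr$es, 4), " over ", length(query), " query genes")
  list(consensus = cons, enrichment = enr, atac_metric = running)
}
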