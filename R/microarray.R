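# Probe-level microarray helper: probe averaging, knockout/control
# fold-change ranking, and the top-k down-regulated z-score heatmap matrix.

#' Rank genes by knockout fold change from a probe-level matrix
#'
#' Averages probes per gene, computes `log2(mean_ko / mean_control)` of the
#' per-gene sample means (with a small pseudocount for non-positive
#' intensities), and ranks genes ascending — rank 1 is the most
#' down-regulated. The z-score matrix of the `top_k` most down-regulated
#' genes is returned alongside, the display matrix of an expression heatmap.
#'
#' @param mat numeric probe x sample matrix (expression intensities).
#' @param gene_ids gene symbol per probe row.
#' @param ko_cols,control_cols column names (or indices) per condition.
#' @param top_k rows of the z-score heatmap (default 20).
#' @param pseudocount added before the log ratio (default 1e-3).
#' @return list: `ranking` (data.frame `gene_id`, `log2fc`, `rank`) and
#'   `zscores` (top_k x samples matrix).
#' @export
microarray_down_ranking <- function(mat, gene_ids, ko_cols, control_cols,
                                    top_k = 20, pseudocount = 1e-3) {
  stopifnot(nrow(mat) == length(gene_ids))
  gm <- rowsum(mat, group = gene_ids, reorder = FALSE) /
    as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
  mk <- rowMeans(gm[, ko_cols, drop = FALSE])
  mc <- rowMeans(gm[, control_cols, drop = FALSE])
  lfc <- log2((pmax(mk, 0) + pseudocount) / (pmax(mc, 0) + pseudocount))
  o <- order(lfc, rownames(gm))
  ranking <- data.frame(gene_id = rownames(gm)[o], log2fc = lfc[o],
                        rank = seq_along(o), stringsAsFactors = FALSE)
  pick <- ranking$gene_id[seq_len(min(top_k, nrow(ranking)))]
  z <- zscore_matrix(gm[pick, , drop = FALSE], pick)
  list(ranking = ranking, zscores = z)
}
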