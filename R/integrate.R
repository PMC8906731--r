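# Per-gene occupancy quantification and occupancy-vs-expression integration.

#' Filter non-expressed genes
#'
#' Drops genes with RPKM below `min_rpkm` in every sample.
#'
#' @param expr expression data.frame (`gene_id` + RPKM columns, optionally
#'   `p_value`).
#' @param min_rpkm expression floor in RPKM (default 1).
#' @param rpkm_cols names of the RPKM columns; default all columns except
#'   `gene_id` and `p_value`.
#' @return the filtered data.frame.
#' @export
filter_expressed <- function(expr, min_rpkm = 1, rpkm_cols = NULL) {
  stopifnot(nrow(expr) > 0)
  if (is.null(rpkm_cols))
    rpkm_cols <- setdiff(names(expr), c("gene_id", "p_value"))
  m <- as.matrix(expr[rpkm_cols])
  expr[apply(m >= min_rpkm, 1, any), , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; each adjusted value is at least its raw p-value
#' and monotone in the sorted order.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return vector of q-values in `[0, 1]`.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Classify differential regulation
#'
#' A gene is `down` when FDR < `fdr_threshold` and log2FC <= `-fc_threshold`,
#' `up` when FDR < `fdr_threshold` and log2FC >= `fc_threshold`, otherwise
#' `ns`. The FDR gate is strict, the fold-change gate inclusive.
#'
#' @param log2fc log2 fold change (knockout over control).
#' @param fdr BH-adjusted p-value in `[0, 1]`.
#' @param fc_threshold absolute log2FC threshold (default 1).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return character vector in `{down, up, ns}`.
#' @export
classify_regulation <- function(log2fc, fdr, fc_threshold = 1,
                                fdr_threshold = 0.05) {
  stopifnot(all(fdr >= 0 & fdr <= 1))
  out <- rep("ns", length(log2fc))
  out[fdr < fdr_threshold & log2fc <= -fc_threshold] <- "down"
  out[fdr < fdr_threshold & log2fc >= fc_threshold] <- "up"
  out
}

#' Log2 fold change from replicate RPKMs
#'
#' `log2((mean_ko + c) / (mean_control + c))` with pseudocount
#' `c = 0.01` RPKM.
#'
#' @param expr expression data.frame.
#' @param ko_cols,control_cols RPKM column names per condition.
#' @param pseudocount pseudocount in RPKM (default 0.01).
#' @return numeric vector of log2 fold changes.
#' @export
expression_log2fc <- function(expr, ko_cols, control_cols, pseudocount = 0.01) {
  mk <- rowMeans(as.matrix(expr[ko_cols]))
  mc <- rowMeans(as.matrix(expr[control_cols]))
  log2((mk + pseudocount) / (mc + pseudocount))
}

# sum over genes of background-subtracted peak AUC for peaks whose summit
# falls in [tss - lo, tss + hi] windows; shared worker for promoter/distal.
sum_signal_in_window <- function(genes, peaks, within, exclude = 0,
                                 subtract_background = TRUE) {
  out <- numeric(nrow(genes))
  if (nrow(peaks) == 0) return(out)
  val <- if (subtract_background) {
    background_subtracted_auc(peaks$auc, peaks$background_auc)
  } else peaks$auc
  for (cn in unique(genes$chrom)) {
    gi <- which(genes$chrom == cn)
    pk <- which(peaks$chrom == cn)
    if (!length(pk)) next
    q <- IRanges::IRanges(start = genes$tss[gi] - within, end = genes$tss[gi] + within)
    s <- IRanges::IRanges(start = peaks$summit[pk], width = 1L)
    hit <- IRanges::findOverlaps(q, s)
    if (!length(hit)) next
    g <- S4Vectors::queryHits(hit); p <- S4Vectors::subjectHits(hit)
    if (exclude > 0) {
      keep <- abs(peaks$summit[pk][p] - genes$tss[gi][g]) > exclude
      g <- g[keep]; p <- p[keep]
    }
    if (length(g)) {
      sums <- tapply(val[pk][p], g, sum)
      out[gi[as.integer(names(sums))]] <- out[gi[as.integer(names(sums))]] +
        as.numeric(sums)
    }
  }
  out
}

#' Gene-level promoter occupancy signal
#'
#' Sum of background-subtracted peak AUCs over all peaks whose summit lies
#' within `window` bp of the gene's TSS.
#'
#' @param genes gene-model data.frame (`gene_id`, `chrom`, `strand`, `tss`).
#' @param peaks peak data.frame with `summit`, `auc`, `background_auc`.
#' @param window promoter half-width in bp (default 2000).
#' @return numeric vector of signal (signal x bp), one per gene.
#' @export
gene_promoter_signal <- function(genes, peaks, window = 2000) {
  stopifnot(window >= 0)
  sum_signal_in_window(genes, peaks, within = window)
}

#' Gene-level distal occupancy signal
#'
#' Sum of background-subtracted peak AUCs over peaks with summit within
#' `far_limit` of the TSS but outside the promoter (`+/- promoter_window`).
#'
#' @inheritParams gene_promoter_signal
#' @param far_limit distal search radius in bp (default 1 Mb).
#' @param promoter_window excluded promoter half-width (default 2000).
#' @return numeric vector of signal (signal x bp), one per gene.
#' @export
gene_distal_signal <- function(genes, peaks, far_limit = 1e6,
                               promoter_window = 2000) {
  stopifnot(far_limit > promoter_window)
  sum_signal_in_window(genes, peaks, within = far_limit,
                       exclude = promoter_window)
}

#' Rank-binned occupancy-versus-expression trend
#'
#' Genes are ranked by occupancy signal (descending, ties broken by gene id)
#' and split into `n_bins` contiguous bins of near-equal size (the remainder
#' spread over the leading bins); per-bin medians of signal and log2FC trace
#' the occupancy-expression trend.
#'
#' @param gene_id character vector of gene ids.
#' @param signal per-gene occupancy signal.
#' @param log2fc per-gene log2 fold change.
#' @param n_bins number of bins (default 1000; must be <= number of genes).
#' @return data.frame: `bin_index`, `n_genes`, `median_signal`,
#'   `median_log2fc`.
#' @export
binned_occupancy_trend <- function(gene_id, signal, log2fc, n_bins = 1000) {
  n <- length(gene_id)
  stopifnot(length(signal) == n, length(log2fc) == n, n_bins >= 1)
  if (n_bins > n) stop("n_bins exceeds the number of genes")
  o <- order(-signal, gene_id)
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  bin <- rep(seq_len(n_bins), times = sizes)
  data.frame(
    bin_index = seq_len(n_bins),
    n_genes = sizes,
    median_signal = as.numeric(tapply(signal[o], bin, stats::median)),
    median_log2fc = as.numeric(tapply(log2fc[o], bin, stats::median))
  )
}

#' Per-gene expression z-scores across samples
#'
#' Rows with duplicate gene ids (e.g. microarray probes) are averaged before
#' z-scoring; each retained row is centered and scaled by its sample
#' standard deviation (n - 1). Zero-variance rows become zeros with a
#' warning.
#'
#' @param mat numeric matrix, rows = probes/genes, columns = samples (>= 2).
#' @param gene_ids gene id per row (default rownames); duplicates averaged.
#' @return matrix of z-scores, one row per distinct gene.
#' @export
zscore_matrix <- function(mat, gene_ids = rownames(mat)) {
  stopifnot(ncol(mat) >= 2, !is.null(gene_ids))
  m <- rowsum(mat, group = gene_ids, reorder = FALSE) /
    as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene row(s) set to zero")
    sd[flat] <- 1
  }
  z <- (m - mu) / sd
  z[flat, ] <- 0
  z
}

#' Top down-regulated genes as a z-score heatmap matrix
#'
#' Selects the `top_k` most down-regulated significant genes (lowest log2FC
#' with FDR below the threshold), averages duplicate probe rows, and returns
#' per-gene z-scores across samples — the display matrix of an
#' expression heatmap.
#'
#' @param mat numeric matrix, rows = probes, columns = samples.
#' @param gene_ids gene id per row.
#' @param log2fc per-distinct-gene log2 fold change (named by gene id, or in
#'   `unique(gene_ids)` order).
#' @param fdr per-distinct-gene FDR (same order).
#' @param top_k number of genes (default 20).
#' @param fdr_threshold significance gate (default 0.05).
#' @param direction `"down"` (default) or `"up"`.
#' @return z-score matrix with `top_k` (or fewer) rows.
#' @export
top_regulated_zscores <- function(mat, gene_ids, log2fc, fdr, top_k = 20,
                                  fdr_threshold = 0.05, direction = c("down", "up")) {
  direction <- match.arg(direction)
  ug <- unique(gene_ids)
  if (is.null(names(log2fc))) names(log2fc) <- ug
  if (is.null(names(fdr))) names(fdr) <- ug
  sig <- ug[fdr[ug] < fdr_threshold]
  ord <- if (direction == "down") order(log2fc[sig]) else order(-log2fc[sig])
  pick <- sig[ord][seq_len(min(top_k, length(sig)))]
  keep <- gene_ids %in% pick
  z <- zscore_matrix(mat[keep, , drop = FALSE], gene_ids[keep])
  z[pick, , drop = FALSE]
}

#' Occupancy matrix around anchor coordinates
#'
#' Each row is the per-column mean signal over the `+/- flank` window around
#' an anchor (a peak center or TSS), split into `n_cols` equal-width bins;
#' rows are sorted descending either by the window's total signal
#' (`"region_sum"`) or by a supplied per-anchor score (`"anchor_signal"`).
#' The column-wise mean of the matrix is the meta profile.
#'
#' @param anchors data.frame with `chrom` and `pos` (anchor coordinate).
#' @param track a [signal_track].
#' @param flank half-window in bp (default 5000).
#' @param n_cols number of columns (default 50).
#' @param row_order `"region_sum"` (default) or `"anchor_signal"`.
#' @param anchor_score per-anchor score, required for `"anchor_signal"`.
#' @return list with `matrix` (rows sorted) and `meta` (column means).
#' @export
occupancy_matrix <- function(anchors, track, flank = 5000, n_cols = 50,
                             row_order = c("region_sum", "anchor_signal"),
                             anchor_score = NULL) {
  row_order <- match.arg(row_order)
  stopifnot(flank > 0, n_cols >= 1)
  w <- 2L * as.integer(flank)
  col_of <- floor((seq_len(w) - 1L) * n_cols / w) + 1L
  n <- nrow(anchors)
  m <- matrix(0, n, n_cols)
  for (i in seq_len(n)) {
    v <- track_values(track, anchors$chrom[i],
                      anchors$pos[i] - as.integer(flank),
                      anchors$pos[i] + as.integer(flank))
    m[i, ] <- as.numeric(tapply(v, col_of, mean))
  }
  key <- if (row_order == "region_sum") {
    rowSums(m)
  } else {
    if (is.null(anchor_score)) stop("anchor_score required for row_order = 'anchor_signal'")
    anchor_score
  }
  o <- order(-key)
  list(matrix = m[o, , drop = FALSE], meta = colMeans(m), order = o)
}

#' Mann-Whitney comparison of signal between regulation classes
#'
#' Two-sided Mann-Whitney U tests of occupancy signal for each pair of
#' regulation classes (down vs ns, up vs ns, down vs up). Pairs with an
#' empty group are skipped with a warning.
#'
#' @param signal per-gene occupancy signal.
#' @param reg_class per-gene class in `{down, up, ns}`.
#' @return data.frame: `group_a`, `group_b`, `n_a`, `n_b`, `U`, `p_value`.
#' @export
signal_by_class_test <- function(signal, reg_class) {
  pairs <- list(c("down", "ns"), c("up", "ns"), c("down", "up"))
  rows <- lapply(pairs, function(pr) {
    a <- signal[reg_class == pr[1]]
    b <- signal[reg_class == pr[2]]
    if (!length(a) || !length(b)) {
      warning("empty group in comparison ", pr[1], " vs ", pr[2], "; skipped")
      return(NULL)
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    data.frame(group_a = pr[1], group_b = pr[2], n_a = length(a),
               n_b = length(b), U = unname(wt$statistic),
               p_value = wt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
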