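# ATAC-seq consensus peaks, rank dynamics between conditions, and
# running-sum leading-edge enrichment.

#' Merge two condition peak sets into consensus peaks
#'
#' Overlapping intervals (>= 1 bp, transitively) are unioned; per-condition
#' mean AUC over replicates is then recomputed on each consensus interval —
#' from the condition's coverage tracks when given, otherwise as the sum of
#' the member input peaks' AUCs per condition.
#'
#' @param peaks_control,peaks_ko peak data.frames for the two conditions.
#' @param tracks_control,tracks_ko optional lists of replicate
#'   [signal_track]s used to recompute AUC on the consensus intervals.
#' @param tf_peaks optional anchor-TF peak data.frame; each consensus peak
#'   gets `anchor_tf_auc`, the summed background-subtracted AUC of TF peaks
#'   whose summit falls inside it.
#' @return data.frame: `chrom`, `start`, `end`, `name`, `mean_auc_control`,
#'   `mean_auc_ko`, `anchor_tf_auc`.
#' @export
merge_consensus <- function(peaks_control, peaks_ko,
                            tracks_control = NULL, tracks_ko = NULL,
                            tf_peaks = NULL) {
  if ((is.null(peaks_control) || nrow(peaks_control) == 0) &&
      (is.null(peaks_ko) || nrow(peaks_ko) == 0))
    stop("both peak sets are empty")
  parts <- Filter(function(p) !is.null(p) && nrow(p) > 0,
                  list(peaks_control, peaks_ko))
  all_pk <- do.call(rbind, lapply(parts, function(p) p[c("chrom", "start", "end")]))
  # min.gapwidth = 0: merge on >= 1 bp overlap only, not mere adjacency
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    all_pk$chrom, IRanges::IRanges(all_pk$start + 1L, all_pk$end)),
    min.gapwidth = 0L)
  gr <- GenomicRanges::sort(gr)
  cons <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  cons$name <- sprintf("consensus_%d", seq_len(nrow(cons)))

  mean_auc <- function(tracks, peaks) {
    if (!is.null(tracks)) {
      per_rep <- vapply(tracks, function(tr)
        vapply(seq_len(nrow(cons)), function(i)
          peak_auc(tr, cons$chrom[i], cons$start[i], cons$end[i]), numeric(1)),
        numeric(nrow(cons)))
      rowMeans(matrix(per_rep, nrow = nrow(cons)))
    } else {
      assign_sum(cons, peaks, peaks$auc)
    }
  }
  cons$mean_auc_control <- mean_auc(tracks_control, peaks_control)
  cons$mean_auc_ko <- mean_auc(tracks_ko, peaks_ko)
  cons$anchor_tf_auc <- if (is.null(tf_peaks) || nrow(tf_peaks) == 0) {
    0
  } else {
    assign_sum(cons, tf_peaks,
               background_subtracted_auc(tf_peaks$auc, tf_peaks$background_auc))
  }
  cons
}

# sum `val` of member peaks whose summit falls inside each consensus interval
assign_sum <- function(cons, peaks, val) {
  out <- numeric(nrow(cons))
  if (is.null(peaks) || nrow(peaks) == 0) return(out)
  q <- GenomicRanges::GRanges(cons$chrom,
                              IRanges::IRanges(cons$start + 1L, cons$end))
  s <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$summit + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(q, s)
  if (length(hit)) {
    sums <- tapply(val[S4Vectors::subjectHits(hit)], S4Vectors::queryHits(hit), sum)
    out[as.integer(names(sums))] <- as.numeric(sums)
  }
  out
}

#' Rank consensus peaks within each condition
#'
#' Ascending ranks by mean AUC per condition; ties broken by chromosome and
#' interval start for determinism. Adds `rank_control`, `rank_ko` and
#' `rank_change` (= `rank_control - rank_ko`, positive when the peak falls
#' in the knockout ranking).
#'
#' @param consensus consensus-peak data.frame from [merge_consensus()].
#' @return the data.frame with rank columns added.
#' @export
rank_peaks <- function(consensus) {
  rank_by <- function(x) {
    o <- order(x, consensus$chrom, consensus$start)
    r <- integer(length(x)); r[o] <- seq_along(x); r
  }
  consensus$rank_control <- rank_by(consensus$mean_auc_control)
  consensus$rank_ko <- rank_by(consensus$mean_auc_ko)
  consensus$rank_change <- consensus$rank_control - consensus$rank_ko
  consensus
}

#' Per-gene promoter accessibility signal
#'
#' Sum of raw (not background-subtracted) ATAC peak AUCs whose summit lies
#' within `window` bp of the gene's TSS.
#'
#' @param genes gene-model data.frame.
#' @param atac_peaks ATAC peak data.frame with `summit` and `auc`.
#' @param window promoter half-width in bp (default 2000).
#' @return numeric vector, one value per gene.
#' @export
promoter_atac_signal <- function(genes, atac_peaks, window = 2000) {
  stopifnot(window >= 0)
  sum_signal_in_window(genes, atac_peaks, within = window,
                       subtract_background = FALSE)
}

#' Accessibility-change ranking metric
#'
#' `log2((control + pseudocount) / (ko + pseudocount))`: larger values mean
#' greater accessibility loss in the knockout.
#'
#' @param control,ko per-gene promoter accessibility signals (>= 0).
#' @param pseudocount additive pseudocount in signal x bp (default 1).
#' @return numeric vector of log2 ratios.
#' @export
atac_rank_metric <- function(control, ko, pseudocount = 1) {
  stopifnot(all(control >= 0), all(ko >= 0), pseudocount > 0)
  log2((control + pseudocount) / (ko + pseudocount))
}

#' Running-sum leading-edge enrichment of a gene set
#'
#' Walks the ranked gene list: at members of the query set the running sum
#' rises by `|metric|^weight_exponent` normalized by the sum over all hits;
#' at non-members it falls by `1/(N - |S|)`. The enrichment score is the
#' signed maximum deviation from zero; the leading edge is the hits at or
#' before the positive extremum (or at/after the negative one).
#'
#' @param gene_ids gene ids ordered by the ranking metric, descending.
#' @param metric the per-gene ranking metric, same order.
#' @param query_set character vector of gene ids (non-empty subset of
#'   `gene_ids`).
#' @param weight_exponent hit-weight exponent (default 1; 0 gives the
#'   classic unweighted statistic).
#' @param n_perm optional number of seeded gene-set permutations for an
#'   empirical p-value (0 = none).
#' @return list: `es`, `leading_edge`, `running_sum`, and `p_value` when
#'   permutations are requested.
#' @export
enrichment_score <- function(gene_ids, metric, query_set, weight_exponent = 1,
                             n_perm = 0) {
  n <- length(gene_ids)
  stopifnot(length(metric) == n)
  hit <- gene_ids %in% query_set
  if (!length(query_set) || !any(hit))
    stop("query set is empty or disjoint from the ranked list")
  if (all(hit)) stop("query set covers the whole ranked list")
  score_of <- function(hit) {
    w <- abs(metric)^weight_exponent
    w[!hit] <- 0
    nr <- sum(w)
    if (nr == 0) { # all hit weights zero (e.g. flat metric): equal weights
      w[hit] <- 1
      nr <- sum(w)
    }
    step <- w / nr
    step[!hit] <- -1 / (n - sum(hit))
    cumsum(step)
  }
  rs <- score_of(hit)
  i_ext <- which.max(abs(rs))
  es <- rs[i_ext]
  le <- if (es >= 0) {
    gene_ids[seq_len(i_ext)][hit[seq_len(i_ext)]]
  } else {
    gene_ids[i_ext:n][hit[i_ext:n]]
  }
  out <- list(es = es, leading_edge = le, running_sum = rs)
  if (n_perm > 0) {
    k <- sum(hit)
    perm <- vapply(seq_len(n_perm), function(i) {
      h <- logical(n); h[sample.int(n, k)] <- TRUE
      rs_p <- score_of(h)
      rs_p[which.max(abs(rs_p))]
    }, numeric(1))
    out$p_value <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
  }
  out
}
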