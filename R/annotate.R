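# Promoter/enhancer/other classification and distance-to-TSS statistics.

# nearest TSS for positions on one chromosome; genes_tss sorted ascending.
nearest_tss_idx <- function(pos, tss_sorted) {
  i <- findInterval(pos, tss_sorted)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(tss_sorted))
  d_lo <- abs(pos - tss_sorted[lo])
  d_hi <- abs(pos - tss_sorted[hi])
  ifelse(d_lo <= d_hi, lo, hi)
}

# per-peak nearest gene and distance (summit-based); Inf on chromosomes
# without annotated genes.
nearest_gene <- function(peaks, genes) {
  n <- nrow(peaks)
  gene <- rep(NA_character_, n)
  dist <- rep(Inf, n)
  for (cn in unique(peaks$chrom)) {
    g <- genes[genes$chrom == cn, , drop = FALSE]
    p_idx <- which(peaks$chrom == cn)
    if (!nrow(g)) next
    o <- order(g$tss, g$gene_id)
    tss <- g$tss[o]
    j <- nearest_tss_idx(peaks$summit[p_idx], tss)
    gene[p_idx] <- g$gene_id[o][j]
    dist[p_idx] <- abs(peaks$summit[p_idx] - tss[j])
  }
  list(gene = gene, distance = dist)
}

#' Annotate peaks as promoter, enhancer or other
#'
#' A peak is a promoter peak when its summit lies within `promoter_window`
#' bp of the nearest TSS; otherwise it is an enhancer peak when its interval
#' overlaps any H3K27ac interval by at least 1 bp; otherwise `other`. The
#' categories are mutually exclusive and exhaustive.
#'
#' @param peaks peak data.frame (`chrom`, `start`, `end`, `name`, `summit`).
#' @param genes gene-model data.frame (`gene_id`, `chrom`, `strand`, `tss`).
#' @param h3k27ac data.frame of H3K27ac intervals (`chrom`, `start`, `end`),
#'   or `NULL` (no enhancer calls).
#' @param cpg_islands optional CpG-island intervals for the `cpg_overlap`
#'   flag.
#' @param promoter_window promoter half-width in bp (default 2000).
#' @param distance_limit nearest-TSS distances beyond this are reported `NA`
#'   (default 1 Mb).
#' @return data.frame: `name`, `category`, `nearest_tss_gene`,
#'   `distance_to_tss`, `cpg_overlap`.
#' @export
annotate_peaks <- function(peaks, genes, h3k27ac = NULL, cpg_islands = NULL,
                           promoter_window = 2000, distance_limit = 1e6) {
  if (is.null(genes) || nrow(genes) == 0)
    stop("cannot classify peaks without a gene annotation")
  stopifnot(promoter_window >= 0)
  ng <- nearest_gene(peaks, genes)
  category <- rep("other", nrow(peaks))
  category[ng$distance <= promoter_window] <- "promoter"
  if (!is.null(h3k27ac) && nrow(h3k27ac)) {
    ov <- overlaps_any(peaks, h3k27ac)
    category[category != "promoter" & ov] <- "enhancer"
  }
  cpg <- if (is.null(cpg_islands) || nrow(cpg_islands) == 0) {
    rep(FALSE, nrow(peaks))
  } else overlaps_any(peaks, cpg_islands)
  data.frame(name = peaks$name,
             category = factor(category, levels = c("promoter", "enhancer", "other")),
             nearest_tss_gene = ng$gene,
             distance_to_tss = ifelse(ng$distance <= distance_limit,
                                      ng$distance, NA_real_),
             cpg_overlap = cpg, stringsAsFactors = FALSE)
}

# >=1 bp interval overlap of peaks with an interval set
overlaps_any <- function(peaks, intervals) {
  q <- GenomicRanges::GRanges(peaks$chrom,
                              IRanges::IRanges(peaks$start + 1L, peaks$end))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start + 1L, intervals$end))
  GenomicRanges::countOverlaps(q, s) > 0
}

#' Fraction of peaks overlapping CpG islands
#'
#' @param peaks peak data.frame.
#' @param cpg_islands CpG-island intervals (`chrom`, `start`, `end`).
#' @return fraction in `[0, 1]` of peaks with >= 1 bp overlap.
#' @export
cpg_overlap_fraction <- function(peaks, cpg_islands) {
  if (nrow(peaks) == 0) stop("overlap fraction undefined for an empty peak set")
  if (is.null(cpg_islands) || nrow(cpg_islands) == 0) return(0)
  mean(overlaps_any(peaks, cpg_islands))
}

#' Distances from peak summits to the nearest TSS
#'
#' Peaks farther than `limit` from every TSS (or on chromosomes without
#' genes) are excluded, so the output may be shorter than the peak set.
#'
#' @inheritParams annotate_peaks
#' @param limit maximum distance retained (default 1 Mb).
#' @return numeric vector of distances in bp.
#' @export
distances_to_nearest_tss <- function(peaks, genes, limit = 1e6) {
  if (is.null(genes) || nrow(genes) == 0) stop("gene annotation is empty")
  d <- nearest_gene(peaks, genes)$distance
  d[d <= limit]
}

#' Epps-Singleton two-sample test
#'
#' Nonparametric comparison of two distributions through their empirical
#' characteristic functions evaluated at `t / (IQR/2)` of the pooled sample,
#' with `t = (0.4, 0.8)` by default. Unlike rank tests it is consistent for
#' discrete distributions and for differences beyond location. The statistic
#' is asymptotically chi-square with degrees of freedom equal to the rank of
#' the pooled covariance (4 in the regular case); for total n < 25 the
#' standard small-sample correction is applied.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 5.
#' @param t characteristic-function evaluation points before scaling.
#' @return list with `statistic` (W2), `p_value`, and `df`.
#' @export
epps_singleton_test <- function(sample_a, sample_b, t = c(0.4, 0.8)) {
  x <- as.numeric(sample_a); y <- as.numeric(sample_b)
  nx <- length(x); ny <- length(y)
  if (nx < 5 || ny < 5) stop("each sample needs at least 5 observations")
  sigma <- stats::IQR(c(x, y)) / 2
  if (sigma <= 0) stop("pooled semi-interquartile range is zero")
  ts <- t / sigma
  gfun <- function(z) {
    m <- cbind(cos(ts[1] * z), sin(ts[1] * z), cos(ts[2] * z), sin(ts[2] * z))
    m
  }
  gx <- gfun(x); gy <- gfun(y)
  n <- nx + ny
  d <- colMeans(gx) - colMeans(gy)
  # biased (1/n) covariance estimates, as in the original test
  est_cov <- (n / nx) * stats::cov(gx) * (nx - 1) / nx +
    (n / ny) * stats::cov(gy) * (ny - 1) / ny
  # Moore-Penrose inverse via eigen decomposition; rank sets the df
  e <- eigen(est_cov, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  pos <- e$values > tol
  inv <- e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
  w <- n * as.numeric(t(d) %*% inv %*% d)
  if (max(nx, ny) < 25)
    w <- w / (1 + n^(-0.45) + 10.1 * (nx^(-1.7) + ny^(-1.7)))
  df <- sum(pos)
  list(statistic = w, p_value = stats::pchisq(w, df = df, lower.tail = FALSE),
       df = df)
}
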