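# Motif co-occurrence clustering over open chromatin and anchor-factor
# association.

#' Co-occurrence distance between motif columns
#'
#' `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation of the two
#' binary hit vectors (the phi coefficient). Distances lie in `[0, 2]` with
#' a zero diagonal.
#'
#' @param hits binary peaks x factors matrix (>= 3 peaks, >= 2 factors,
#'   unique column names).
#' @return symmetric distance matrix, factors x factors.
#' @export
cooccurrence_distance <- function(hits) {
  hits <- as.matrix(hits)
  if (ncol(hits) < 2) stop("need at least 2 factors")
  if (nrow(hits) < 3) stop("need at least 3 peaks")
  if (anyDuplicated(colnames(hits))) stop("factor names must be unique")
  if (!all(hits %in% c(0, 1))) stop("hit matrix must be binary")
  v <- apply(hits, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance factor column(s): ",
         paste(colnames(hits)[v == 0], collapse = ", "))
  d <- 1 - stats::cor(hits)
  diag(d) <- 0
  d
}

#' Hierarchically cluster motifs by co-occurrence
#'
#' Factors are clustered agglomeratively (average linkage) using the
#' Euclidean distance between their rows of the correlation-distance matrix.
#' Columns are put in lexicographic name order first so ties resolve
#' deterministically; the partition is invariant to input factor order.
#'
#' @param d correlation-distance matrix from [cooccurrence_distance()], or a
#'   binary hit matrix (converted internally).
#' @param n_clusters number of clusters for the cut.
#' @param method `"euclidean_rows"` (default; cluster on rows of `d`) or
#'   `"direct"` (use `d` itself as the dissimilarity).
#' @return list: `labels` (named integer vector), `tree` ([stats::hclust]),
#'   `merge` (merge-table data.frame: `child1`, `child2`, `height`).
#' @export
cluster_motifs <- function(d, n_clusters,
                           method = c("euclidean_rows", "direct")) {
  method <- match.arg(method)
  if (!isSymmetric(unname(as.matrix(d)))) d <- cooccurrence_distance(d)
  d <- as.matrix(d)
  if (n_clusters > ncol(d)) stop("more clusters requested than factors")
  o <- order(colnames(d))
  d <- d[o, o, drop = FALSE]
  dd <- if (method == "euclidean_rows") stats::dist(d) else stats::as.dist(d)
  tree <- stats::hclust(dd, method = "average")
  labels <- stats::cutree(tree, k = n_clusters)
  merge_df <- data.frame(
    child1 = tree$merge[, 1], child2 = tree$merge[, 2],
    height = tree$height)
  list(labels = labels, tree = tree, merge = merge_df)
}

#' Per-factor association with anchor-overlapping peaks
#'
#' Odds ratio of the 2x2 table (motif hit vs no hit) x (peak overlaps the
#' anchor factor vs not). When any cell is zero the Haldane correction adds
#' 0.5 to every cell.
#'
#' @param hits binary peaks x factors matrix.
#' @param anchor logical/0-1 vector: does each peak overlap the anchor
#'   factor's peak set.
#' @return data.frame: `factor`, `odds_ratio`, the four table cells, and
#'   `corrected` (whether Haldane was applied).
#' @export
anchor_association <- function(hits, anchor) {
  hits <- as.matrix(hits)
  anchor <- as.logical(anchor)
  stopifnot(length(anchor) == nrow(hits))
  if (all(anchor) || !any(anchor))
    stop("anchor overlap must split the peaks into two non-empty groups")
  rows <- lapply(colnames(hits), function(f) {
    h <- hits[, f] == 1
    a <- sum(h & anchor); b <- sum(h & !anchor)
    cc <- sum(!h & anchor); dd <- sum(!h & !anchor)
    corr <- any(c(a, b, cc, dd) == 0)
    if (corr) {
      or <- ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      or <- (a * dd) / (b * cc)
    }
    data.frame(factor = f, odds_ratio = or, hit_anchor = a, hit_other = b,
               nohit_anchor = cc, nohit_other = dd, corrected = corr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
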