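# Plain-text readers/writers for the formats the pipeline touches. All
# coordinates are kept 0-based half-open, as in the files themselves.

#' Read a BED file of intervals
#'
#' BED3/BED6; only `chrom`, `start`, `end` (and `name`, `strand` when
#' present) are retained.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end` (+ `name`, `strand`).
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  out <- data.frame(chrom = as.character(x[[1]]), start = as.integer(x[[2]]),
                    end = as.integer(x[[3]]), stringsAsFactors = FALSE)
  if (ncol(x) >= 4) out$name <- as.character(x[[4]])
  if (ncol(x) >= 6) out$strand <- as.character(x[[6]])
  out
}

#' Read reads from a BED6 file
#'
#' Name and score columns are ignored; strand is required.
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end`, `strand`.
#' @export
read_reads_bed <- function(path) {
  x <- read_bed(path)
  if (is.null(x$strand)) stop("BED6 with a strand column is required for reads")
  x[, c("chrom", "start", "end", "strand")]
}

#' Read peaks from BED6 or narrowPeak
#'
#' For narrowPeak (10 columns) the summit is `start` + column-10 offset; a
#' -1 offset, or plain BED input, falls back to the interval midpoint.
#'
#' @param path file path.
#' @return peak data.frame: `chrom`, `start`, `end`, `name`, `summit`,
#'   `auc`, `background_auc` (AUC columns zero-initialized).
#' @export
read_peaks <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  chrom <- as.character(x[[1]]); start <- as.integer(x[[2]]); end <- as.integer(x[[3]])
  name <- if (ncol(x) >= 4) as.character(x[[4]]) else sprintf("peak_%d", seq_along(chrom))
  summit <- as.integer(floor((start + end) / 2))
  if (ncol(x) >= 10) {
    off <- as.integer(x[[10]])
    has <- !is.na(off) & off >= 0
    summit[has] <- start[has] + off[has]
  }
  auc <- if (ncol(x) >= 7) suppressWarnings(as.numeric(x[[7]])) else rep(0, length(chrom))
  auc[is.na(auc)] <- 0
  data.frame(chrom = chrom, start = start, end = end, name = name,
             summit = summit, auc = auc, background_auc = 0,
             stringsAsFactors = FALSE)
}

#' Write peaks as narrowPeak
#'
#' Column 7 (signalValue) carries the peak AUC; column 10 the summit offset.
#'
#' @param peaks peak data.frame.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                   0L, ".", signif(peaks$auc, 8), -1, -1,
                   peaks$summit - peaks$start)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a bedGraph coverage track
#'
#' Stepwise run-length input; gaps are zero. Returns a [signal_track].
#'
#' @param path file path.
#' @param total_mapped total mapped reads to attach (default `NA`).
#' @param chrom_lengths optional named lengths; default max `end` per chrom.
#' @return a [signal_track].
#' @export
read_bedgraph <- function(path, total_mapped = NA_real_, chrom_lengths = NULL) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#",
                         col.names = c("chrom", "start", "end", "value"))
  track_from_segments(x, total_mapped = total_mapped, chrom_lengths = chrom_lengths)
}

#' Signal track from stepwise segments
#'
#' @param segments data.frame `chrom`, `start`, `end`, `value` (half-open,
#'   non-overlapping within a chromosome).
#' @inheritParams read_bedgraph
#' @return a [signal_track].
#' @export
track_from_segments <- function(segments, total_mapped = NA_real_,
                                chrom_lengths = NULL) {
  chroms <- if (is.null(chrom_lengths)) unique(segments$chrom) else names(chrom_lengths)
  cov <- lapply(chroms, function(cn) {
    s <- segments[segments$chrom == cn, , drop = FALSE]
    len <- if (is.null(chrom_lengths)) {
      if (nrow(s)) max(s$end) else 0L
    } else as.integer(chrom_lengths[[cn]])
    r <- S4Vectors::Rle(0, len)
    if (nrow(s)) {
      s <- s[order(s$start), , drop = FALSE]
      keep <- s$start < len & s$end > 0
      s <- s[keep, , drop = FALSE]
      ends <- pmin(s$end, len); starts <- pmax(s$start, 0L)
      if (any(starts < c(0L, utils::head(ends, -1))))
        stop("overlapping bedGraph segments on ", cn)
      # interleave zero gaps with segment runs, then drop empty runs
      gaps <- starts - c(0L, utils::head(ends, -1))
      run_len <- as.vector(rbind(gaps, ends - starts))
      run_val <- as.vector(rbind(0, s$value))
      run_len <- c(run_len, len - ends[length(ends)])
      run_val <- c(run_val, 0)
      keep <- run_len > 0
      r <- S4Vectors::Rle(run_val[keep], run_len[keep])
    }
    r
  })
  names(cov) <- chroms
  signal_track(cov, total_mapped)
}

#' Write a signal track as bedGraph
#'
#' Zero runs are omitted, as usual for sparse tracks.
#'
#' @param track a [signal_track].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$cov), function(cn) {
    r <- track$cov[[cn]]
    v <- S4Vectors::runValue(r); l <- S4Vectors::runLength(r)
    end <- cumsum(as.numeric(l)); start <- end - l
    keep <- v != 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = cn, start = as.integer(start[keep]),
               end = as.integer(end[keep]), value = signif(v[keep], 8),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a TSS/gene annotation table
#'
#' TSV with header columns `gene_id`, `chrom`, `strand`, `tss`.
#'
#' @param path file path.
#' @return data.frame of gene models.
#' @export
read_tss_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss")
  if (!all(need %in% names(x))) stop("TSS table needs columns: ",
                                     paste(need, collapse = ", "))
  if (anyDuplicated(x$gene_id)) stop("duplicate gene_id in TSS table")
  x[, need]
}

#' @rdname read_tss_table
#' @param genes gene-model data.frame.
#' @export
write_tss_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a per-gene expression table
#'
#' TSV with header: `gene_id`, then RPKM columns named `<condition>_<rep>`
#' (e.g. `control_1`, `ko_2`), optionally `p_value`.
#'
#' @param path file path.
#' @return data.frame; RPKM column names are everything except `gene_id`
#'   and `p_value`.
#' @export
read_expression_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(x)) stop("expression table needs a gene_id column")
  x
}

#' Read a binary motif hit matrix
#'
#' TSV with header; first column the peak id, columns prefixed `anchor_`
#' are 0/1 anchor-overlap flags, remaining columns are 0/1 motif hits.
#'
#' @param path file path.
#' @return list with `hits` (binary matrix, rownames = peak ids) and
#'   `anchors` (data.frame of anchor flags).
#' @export
read_motif_hits <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(x[[1]]); x <- x[-1]
  is_anchor <- grepl("^anchor_", names(x))
  hits <- as.matrix(x[!is_anchor])
  rownames(hits) <- ids
  if (!all(hits %in% c(0, 1))) stop("motif hit matrix must be binary")
  anchors <- x[is_anchor]
  rownames(anchors) <- ids
  list(hits = hits, anchors = anchors)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
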