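# All genomic coordinates in this package are 0-based, half-open [start, end),
# the BED convention. Rle vectors are 1-based internally; the conversion is
# confined to this file.

#' Construct a signal track
#'
#' A signal track is per-base coverage (counts or density) over one or more
#' chromosomes, stored run-length encoded, plus the total number of mapped
#' reads used for rpm/bp normalization.
#'
#' @param cov named list of [S4Vectors::Rle] vectors (one per chromosome),
#'   all values non-negative.
#' @param total_mapped total mapped reads behind the track, or `NA` when the
#'   track is not read-derived (e.g. an arbitrary density).
#' @return an object of class `signal_track`.
#' @export
signal_track <- function(cov, total_mapped = NA_real_) {
  stopifnot(is.list(cov), length(names(cov)) == length(cov))
  for (nm in names(cov)) {
    if (!inherits(cov[[nm]], "Rle")) cov[[nm]] <- S4Vectors::Rle(as.numeric(cov[[nm]]))
    v <- S4Vectors::runValue(cov[[nm]])
    if (length(v) && min(v) < 0) {
      if (min(v) < -1e-9) stop("negative coverage on ", nm)
      v[v < 0] <- 0 # round-off from weighted coverage sums
      S4Vectors::runValue(cov[[nm]]) <- v
    }
  }
  if (!is.na(total_mapped) && total_mapped <= 0)
    stop("total_mapped must be > 0 when given")
  structure(list(cov = cov, total_mapped = as.numeric(total_mapped)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$cov), "chromosome(s)\n")
  for (nm in names(x$cov))
    cat(sprintf("  %s: %d bp, mean %.4g\n", nm, length(x$cov[[nm]]),
                mean(x$cov[[nm]])))
  if (!is.na(x$total_mapped))
    cat("  total mapped reads:", format(x$total_mapped, big.mark = ","), "\n")
  invisible(x)
}

#' Extend reads in their 3' direction
#'
#' Each tag alignment is lengthened by `extension_bp` beyond its 3' end
#' (downstream for `+` reads, upstream for `-` reads), a fragment-length
#' surrogate standard in ChIP-seq density estimation. Starts are clipped at 0.
#'
#' @param reads data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (`+` or `-`), 0-based half-open.
#' @param extension_bp non-negative extension length in bp (default 200).
#' @return data.frame with columns `chrom`, `start`, `end` of the extended
#'   spans. Records with an unknown strand are dropped with a warning.
#' @export
extend_reads <- function(reads, extension_bp = 200) {
  stopifnot(extension_bp >= 0, all(reads$end > reads$start))
  bad <- !(reads$strand %in% c("+", "-"))
  if (any(bad)) {
    warning(sum(bad), " read(s) with unknown strand dropped")
    reads <- reads[!bad, , drop = FALSE]
  }
  start <- ifelse(reads$strand == "+", reads$start, pmax(0L, reads$start - extension_bp))
  end <- ifelse(reads$strand == "+", reads$end + extension_bp, reads$end)
  data.frame(chrom = reads$chrom, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Coverage track from reads
#'
#' Builds per-base coverage from strand-extended reads via [IRanges::coverage].
#'
#' @inheritParams extend_reads
#' @param total_mapped total mapped reads for normalization.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the maximum extended end per chromosome.
#' @return a [signal_track].
#' @export
coverage_track <- function(reads, total_mapped, extension_bp = 200,
                           chrom_lengths = NULL) {
  ext <- extend_reads(reads, extension_bp)
  chroms <- if (is.null(chrom_lengths)) unique(ext$chrom) else names(chrom_lengths)
  cov <- lapply(chroms, function(cn) {
    x <- ext[ext$chrom == cn, , drop = FALSE]
    len <- if (is.null(chrom_lengths)) {
      if (nrow(x)) max(x$end) else 0L
    } else chrom_lengths[[cn]]
    if (!nrow(x)) return(S4Vectors::Rle(0, len))
    ir <- IRanges::IRanges(start = x$start + 1L, end = pmin(x$end, len))
    IRanges::coverage(ir, width = len)
  })
  names(cov) <- chroms
  signal_track(cov, total_mapped)
}

#' Normalized read density over a region
#'
#' Reads overlapping the region are extended by `extension_bp` in the 3'
#' direction; the mean per-base coverage over the region is divided by the
#' number of million mapped reads, giving reads per million mapped reads per
#' base pair (rpm/bp).
#'
#' @inheritParams extend_reads
#' @param region one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param total_mapped total mapped reads (> 0).
#' @return scalar density in rpm/bp.
#' @export
read_density <- function(reads, region, total_mapped, extension_bp = 200) {
  if (is.na(total_mapped) || total_mapped <= 0)
    stop("total_mapped must be > 0 for rpm/bp normalization")
  width <- region$end - region$start
  stopifnot(width > 0)
  if (nrow(reads) == 0) return(0)
  ext <- extend_reads(reads, extension_bp)
  ext <- ext[ext$chrom == region$chrom, , drop = FALSE]
  if (!nrow(ext)) return(0)
  ov <- pmax(0, pmin(ext$end, region$end) - pmax(ext$start, region$start))
  (sum(ov) / width) / (total_mapped / 1e6)
}

# Rle view of [start, end) on one chromosome; out-of-bounds bases are zero.
track_values <- function(track, chrom, start, end) {
  stopifnot(end > start)
  out <- numeric(end - start)
  r <- track$cov[[chrom]]
  if (is.null(r)) return(out)
  len <- length(r)
  lo <- max(start, 0L); hi <- min(end, len)
  if (hi > lo)
    out[(lo - start + 1L):(hi - start)] <- as.numeric(S4Vectors::window(r, lo + 1L, hi))
  out
}

#' Area under the curve of a track over an interval
#'
#' Sum of per-base signal over `[start, end)` (signal x bp). Bases outside
#' the track contribute zero.
#'
#' @param track a [signal_track].
#' @param chrom,start,end the interval, 0-based half-open.
#' @return scalar AUC.
#' @export
peak_auc <- function(track, chrom, start, end) {
  stopifnot(end > start)
  r <- track$cov[[chrom]]
  if (is.null(r)) return(0)
  len <- length(r)
  lo <- max(start, 0L); hi <- min(end, len)
  if (hi <= lo) return(0)
  sum(as.numeric(S4Vectors::window(r, lo + 1L, hi)))
}

#' Background-subtracted peak AUC
#'
#' `max(auc - background_auc, 0)`; negative occupancy is floored at zero.
#'
#' @param auc peak AUC (signal x bp, >= 0).
#' @param background_auc AUC of the background (whole-cell extract) track
#'   over the same interval (>= 0).
#' @return non-negative net AUC, vectorized.
#' @export
background_subtracted_auc <- function(auc, background_auc) {
  stopifnot(all(auc >= 0), all(background_auc >= 0))
  pmax(auc - background_auc, 0)
}

#' AUC of peaks against a pair of tracks
#'
#' Convenience: fills the `auc` and `background_auc` columns of a peak table
#' from a signal track and an optional background track.
#'
#' @param peaks peak data.frame (`chrom`, `start`, `end`, ...).
#' @param track signal [signal_track].
#' @param background optional background [signal_track].
#' @return `peaks` with `auc` and `background_auc` columns set.
#' @export
peaks_with_auc <- function(peaks, track, background = NULL) {
  n <- nrow(peaks)
  auc <- numeric(n); bg <- numeric(n)
  for (i in seq_len(n)) {
    auc[i] <- peak_auc(track, peaks$chrom[i], peaks$start[i], peaks$end[i])
    if (!is.null(background))
      bg[i] <- peak_auc(background, peaks$chrom[i], peaks$start[i], peaks$end[i])
  }
  peaks$auc <- auc
  peaks$background_auc <- bg
  peaks
}
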