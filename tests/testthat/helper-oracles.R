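# Naive, independent implementations used as oracles: per-base loops and
# O(n^2) scans, deliberately unrelated to the package's code paths.

# per-base coverage loop density
oracle_density <- function(reads, region, total_mapped, extension_bp = 200) {
  bases <- numeric(region$end - region$start)
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != region$chrom) next
    if (reads$strand[i] == "+") {
      s <- reads$start[i]; e <- reads$end[i] + extension_bp
    } else {
      s <- max(0, reads$start[i] - extension_bp); e <- reads$end[i]
    }
    for (b in seq(region$start, region$end - 1)) {
      if (b >= s && b < e) bases[b - region$start + 1] <- bases[b - region$start + 1] + 1
    }
  }
  mean(bases) / (total_mapped / 1e6)
}

# per-base sum over a dense vector of track values (index 0-based)
oracle_auc <- function(values, start, end) {
  s <- 0
  for (b in start:(end - 1)) {
    if (b >= 0 && b < length(values)) s <- s + values[b + 1]
  }
  s
}

# textbook O(m^2) BH step-up: q_i = min over j >= i of p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# double loop over all (gene, peak) pairs
oracle_promoter_signal <- function(genes, peaks, window = 2000) {
  out <- numeric(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    for (p in seq_len(nrow(peaks))) {
      if (genes$chrom[g] != peaks$chrom[p]) next
      if (abs(peaks$summit[p] - genes$tss[g]) <= window)
        out[g] <- out[g] + max(peaks$auc[p] - peaks$background_auc[p], 0)
    }
  }
  out
}

oracle_distal_signal <- function(genes, peaks, far_limit = 1e6,
                                 promoter_window = 2000) {
  out <- numeric(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    for (p in seq_len(nrow(peaks))) {
      if (genes$chrom[g] != peaks$chrom[p]) next
      d <- abs(peaks$summit[p] - genes$tss[g])
      if (d <= far_limit && d > promoter_window)
        out[g] <- out[g] + max(peaks$auc[p] - peaks$background_auc[p], 0)
    }
  }
  out
}

oracle_atac_signal <- function(genes, peaks, window = 2000) {
  out <- numeric(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    for (p in seq_len(nrow(peaks))) {
      if (genes$chrom[g] != peaks$chrom[p]) next
      if (abs(peaks$summit[p] - genes$tss[g]) <= window)
        out[g] <- out[g] + peaks$auc[p]
    }
  }
  out
}

# pairwise Pearson correlation distance, element by element
oracle_cor_dist <- function(m) {
  k <- ncol(m)
  d <- matrix(0, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    x <- m[, i]; y <- m[, j]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    d[i, j] <- 1 - r
  }
  d
}

# direct running-sum enumeration of the enrichment score
oracle_es <- function(gene_ids, metric, query, p = 1) {
  hit <- gene_ids %in% query
  nr <- sum(abs(metric[hit])^p)
  run <- 0; best <- 0
  for (i in seq_along(gene_ids)) {
    if (hit[i]) {
      run <- run + if (nr > 0) abs(metric[i])^p / nr else 1 / sum(hit)
    } else {
      run <- run - 1 / (length(gene_ids) - sum(hit))
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# nearest-TSS distance by exhaustive all-pairs minimum
oracle_nearest <- function(peaks, genes) {
  vapply(seq_len(nrow(peaks)), function(i) {
    d <- Inf
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] != peaks$chrom[i]) next
      d <- min(d, abs(peaks$summit[i] - genes$tss[g]))
    }
    d
  }, numeric(1))
}

# sort-and-sweep transitive interval merge
oracle_merge <- function(iv) {
  iv <- iv[order(iv$chrom, iv$start), ]
  out <- iv[0, ]
  for (i in seq_len(nrow(iv))) {
    n <- nrow(out)
    if (n > 0 && out$chrom[n] == iv$chrom[i] && iv$start[i] < out$end[n]) {
      out$end[n] <- max(out$end[n], iv$end[i])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

# random fixtures -----------------------------------------------------------

rand_reads <- function(n, chrom_len = 10000, chrom = "chr1") {
  start <- sample.int(chrom_len - 100, n, replace = TRUE) - 1L
  data.frame(chrom = chrom, start = start,
             end = start + sample(20:80, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

rand_peaks <- function(n, chrom_len = 100000, chroms = c("chr1", "chr2")) {
  chrom <- sample(chroms, n, replace = TRUE)
  summit <- sample.int(chrom_len - 2000, n, replace = TRUE) + 1000L
  w <- sample(100:400, n, replace = TRUE)
  data.frame(chrom = chrom, start = summit - w %/% 2L,
             end = summit - w %/% 2L + w,
             name = sprintf("p%03d", seq_len(n)), summit = summit,
             auc = stats::runif(n, 0, 50),
             background_auc = stats::runif(n, 0, 10),
             stringsAsFactors = FALSE)
}

rand_genes <- function(n, chrom_len = 100000, chroms = c("chr1", "chr2")) {
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             tss = sample.int(chrom_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# small config for fast bundle-based tests; ... overrides any default
small_sim_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_chromosomes = 2, chrom_length = 1.2e7,
                   n_genes = 300, n_peaks_tf_a = 150, n_peaks_tf_b = 150,
                   n_direct_down = 30, n_indirect_up = 30,
                   n_atac_distal = 300, n_motif_peaks = 200)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
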