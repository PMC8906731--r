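# Consensus ATAC peaks, rank shifts between conditions, promoter
# accessibility and the running-sum enrichment score.

mk_atac <- function(start, end, auc, chrom = "chr1", tag = "a") {
  n <- length(start)
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = sprintf("%s%02d", tag, seq_len(n)),
             summit = as.integer((start + end) %/% 2), auc = auc,
             background_auc = 0, stringsAsFactors = FALSE)
}

test_that("overlapping peaks union transitively into consensus intervals", {
  a <- mk_atac(100, 200, 5)
  b <- mk_atac(150, 250, 4, tag = "b")
  cons <- merge_consensus(a, b)
  expect_equal(cons[, c("start", "end")],
               data.frame(start = 100L, end = 250L))
  # disjoint peaks pass through unchanged
  cons2 <- merge_consensus(mk_atac(c(0, 1000), c(100, 1100), c(1, 2)),
                           mk_atac(5000, 5100, 3, tag = "b"))
  expect_equal(nrow(cons2), 3)
  expect_error(merge_consensus(a[0, ], a[0, ]), "empty")
  # chained overlaps A-B, B-C collapse to one interval; compare to the
  # sort-and-sweep oracle on random instances
  set.seed(31)
  for (i in 1:10) {
    s1 <- sort(sample.int(5000, 8)); s2 <- sort(sample.int(5000, 8))
    pa <- mk_atac(s1, s1 + sample(50:500, 8, replace = TRUE), 1)
    pb <- mk_atac(s2, s2 + sample(50:500, 8, replace = TRUE), 1, tag = "b")
    cons3 <- merge_consensus(pa, pb)
    orc <- oracle_merge(rbind(pa[, c("chrom", "start", "end")],
                              pb[, c("chrom", "start", "end")]))
    expect_equal(cons3$start, orc$start)
    expect_equal(cons3$end, orc$end)
    # disjoint cover of the union
    expect_true(all(cons3$start[-1] >= head(cons3$end, -1)))
  }
})

test_that("consensus AUC is recomputed on consensus intervals from tracks", {
  a <- mk_atac(100, 200, 0)
  b <- mk_atac(150, 250, 0, tag = "b")
  # two control replicates: constant 2 and 4 over [100,260) -> mean AUC 450
  seg <- function(v) data.frame(chrom = "chr1", start = 100L, end = 260L, value = v)
  tr_c <- list(track_from_segments(seg(2), chrom_lengths = c(chr1 = 1000L)),
               track_from_segments(seg(4), chrom_lengths = c(chr1 = 1000L)))
  tr_k <- list(track_from_segments(seg(1), chrom_lengths = c(chr1 = 1000L)),
               track_from_segments(seg(1), chrom_lengths = c(chr1 = 1000L)))
  cons <- merge_consensus(a, b, tracks_control = tr_c, tracks_ko = tr_k)
  expect_equal(cons$mean_auc_control, 3 * 150)
  expect_equal(cons$mean_auc_ko, 150)
})

test_that("ranks ascend by mean AUC with deterministic ties", {
  cons <- data.frame(chrom = "chr1", start = c(0L, 100L, 200L),
                     end = c(50L, 150L, 250L), name = c("a", "b", "c"),
                     mean_auc_control = c(5, 2, 9),
                     mean_auc_ko = c(5, 2, 9), stringsAsFactors = FALSE)
  r <- rank_peaks(cons)
  expect_equal(r$rank_control, c(2L, 1L, 3L))
  expect_equal(r$rank_ko, r$rank_control)
  expect_equal(r$rank_change, c(0L, 0L, 0L))
  expect_equal(cor(r$rank_control, r$rank_ko, method = "spearman"), 1)
  # a planted knockout loss at bound peaks drops their rank only
  set.seed(12)
  n <- 400
  auc <- rlnorm(n, 3, 0.5)
  bound <- seq_len(n) <= 80
  cons2 <- data.frame(chrom = "chr1", start = seq_len(n) * 1000L,
                      end = seq_len(n) * 1000L + 500L,
                      name = sprintf("c%03d", seq_len(n)),
                      mean_auc_control = auc,
                      mean_auc_ko = auc * ifelse(bound, 0.5, 1),
                      stringsAsFactors = FALSE)
  r2 <- rank_peaks(cons2)
  expect_gt(median(r2$rank_change[bound]), 0)
  expect_lt(abs(median(r2$rank_change[!bound])), 0.1 * n)
})

test_that("promoter accessibility sums raw AUC in the TSS window", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 10000L, stringsAsFactors = FALSE)
  pk <- mk_atac(9500, 9900, 8)
  expect_equal(promoter_atac_signal(genes, pk), 8)
  expect_equal(promoter_atac_signal(genes, pk[0, ]), 0)
  set.seed(13)
  for (i in 1:10) {
    g <- rand_genes(15)
    p <- rand_peaks(50)
    expect_equal(promoter_atac_signal(g, p, window = 4000),
                 oracle_atac_signal(g, p, window = 4000), tolerance = 1e-9)
  }
})

test_that("accessibility rank metric applies the pseudocount symmetrically", {
  expect_equal(atac_rank_metric(8, 2), log2(3))
  expect_equal(atac_rank_metric(5, 5), 0)
  expect_equal(atac_rank_metric(0, 0), 0)
  expect_true(is.finite(atac_rank_metric(1e6, 0)))
})

test_that("enrichment score matches the running-sum definition", {
  ids <- sprintf("g%02d", 1:20)
  metric <- seq(2, -2, length.out = 20)
  # top-|S| query: perfect concordance, es = 1
  r <- enrichment_score(ids, metric, ids[1:5])
  expect_equal(r$es, 1, tolerance = 1e-12)
  expect_setequal(r$leading_edge, ids[1:5])
  # uniformly spread set, unweighted: compare to the enumeration oracle
  spread <- ids[c(2, 6, 10, 14, 18)]
  r0 <- enrichment_score(ids, metric, spread, weight_exponent = 0)
  expect_equal(r0$es, oracle_es(ids, metric, spread, p = 0), tolerance = 1e-12)
  expect_lt(abs(r0$es), 0.5)
  # reversing the ranking negates the unweighted statistic
  r_rev <- enrichment_score(rev(ids), rev(metric), spread, weight_exponent = 0)
  expect_equal(r_rev$es, -r0$es, tolerance = 1e-12)
  # weighted path against the oracle on random instances
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    idsr <- sprintf("r%03d", seq_len(n))
    met <- sort(rnorm(n), decreasing = TRUE)
    q <- sample(idsr, sample(2:(n - 2), 1))
    for (p in c(0, 1)) {
      expect_equal(enrichment_score(idsr, met, q, weight_exponent = p)$es,
                   oracle_es(idsr, met, q, p = p), tolerance = 1e-12)
    }
  }
  expect_error(enrichment_score(ids, metric, character(0)), "empty")
  expect_error(enrichment_score(ids, metric, c("zz1", "zz2")), "disjoint")
})

test_that("enrichment score stays within [-1, 1] and bounds the running sum", {
  set.seed(18)
  for (i in 1:10) {
    n <- 50
    ids <- sprintf("s%03d", 1:n)
    met <- rnorm(n)
    o <- order(-met)
    q <- sample(ids, 12)
    r <- enrichment_score(ids[o], met[o], q)
    expect_lte(abs(r$es), 1 + 1e-12)
    expect_equal(max(abs(r$running_sum)), abs(r$es), tolerance = 1e-12)
    expect_true(all(r$leading_edge %in% q))
  }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
  set.seed(27)
  for (i in 1:5) {
    n <- sample(30:80, 1)
    ids <- sprintf("g%03d", seq_len(n))
    met <- sort(rnorm(n), decreasing = TRUE)
    q <- sample(ids, sample(5:15, 1))
    mine <- enrichment_score(ids, met, q, weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(stats::setNames(met, ids),
                               selectedStats = which(ids %in% q),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("permutation p-value is small for a planted top-heavy set", {
  set.seed(19)
  ids <- sprintf("g%03d", 1:200)
  metric <- sort(rnorm(200, 0, 1), decreasing = TRUE) + 0.01
  r <- enrichment_score(ids, metric, ids[1:30], n_perm = 200)
  expect_lt(r$p_value, 0.05)
})
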