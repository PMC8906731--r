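# Expression filtering, FDR, regulation classes, gene-level occupancy, the
# binned trend, z-scores, occupancy matrices and class-wise tests.

test_that("non-expressed genes are filtered on the all-samples rule", {
  expr <- data.frame(gene_id = c("a", "b", "c"),
                     control_1 = c(0.5, 0.5, 0), ko_1 = c(0.9, 1.2, 0))
  out <- filter_expressed(expr)
  expect_equal(out$gene_id, "b")
})

test_that("BH adjustment matches the textbook step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(3:200, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("regulation classes follow the FDR and fold-change gates", {
  expect_equal(classify_regulation(-1.2, 0.01), "down")
  expect_equal(classify_regulation(1.0, 0.04), "up")   # inclusive FC boundary
  expect_equal(classify_regulation(-0.5, 0.001), "ns") # FC gate fails
  expect_equal(classify_regulation(-1.0, 0.05), "ns")  # strict FDR boundary
  expect_equal(classify_regulation(c(-2, 2, 0), c(0.01, 0.01, 0.01)),
               c("down", "up", "ns"))
})

test_that("promoter and distal gene signal match the all-pairs oracle", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 10000L, stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = c(9400L, 12800L),
                      end = c(9600L, 13200L), name = c("A", "B"),
                      summit = c(9500L, 13000L), auc = c(12, 50),
                      background_auc = c(2, 0), stringsAsFactors = FALSE)
  expect_equal(gene_promoter_signal(genes, peaks), 10)
  expect_equal(gene_promoter_signal(genes, peaks[0, ]), 0)
  # distal window keeps [promoter_window, far_limit] only
  dp <- data.frame(chrom = "chr1", start = 0L, end = 1L, name = "d",
                   summit = c(510000L, 11500L, 1210000L), auc = 7,
                   background_auc = 1, stringsAsFactors = FALSE)
  expect_equal(gene_distal_signal(genes, dp[1, ]), 6)
  expect_equal(gene_distal_signal(genes, dp[2, ]), 0) # promoter-excluded
  expect_equal(gene_distal_signal(genes, dp[3, ]), 0) # beyond 1 Mb
  set.seed(8)
  for (i in 1:15) {
    genes <- rand_genes(20)
    peaks <- rand_peaks(60)
    expect_equal(gene_promoter_signal(genes, peaks, window = 5000),
                 oracle_promoter_signal(genes, peaks, window = 5000),
                 tolerance = 1e-9)
    expect_equal(gene_distal_signal(genes, peaks, far_limit = 40000,
                                    promoter_window = 5000),
                 oracle_distal_signal(genes, peaks, far_limit = 40000,
                                      promoter_window = 5000),
                 tolerance = 1e-9)
  }
})

test_that("binned trend bins by descending signal with stable remainders", {
  tr <- binned_occupancy_trend(c("a", "b", "c", "d"), c(10, 8, 2, 1),
                               c(-2, -1.5, 0.1, 0.2), n_bins = 2)
  expect_equal(tr$median_log2fc, c(-1.75, 0.15))
  expect_equal(tr$median_signal, c(9, 1.5))
  tr1 <- binned_occupancy_trend(c("a", "b", "c"), c(3, 1, 2), c(1, 2, 3), 1)
  expect_equal(tr1$median_log2fc, 2)
  expect_error(binned_occupancy_trend(c("a", "b"), 1:2, 1:2, 3), "n_bins")
  # remainder genes go to the leading bins; input order is irrelevant
  set.seed(2)
  n <- 103
  sig <- runif(n); fc <- rnorm(n); ids <- sprintf("g%03d", 1:n)
  tr7 <- binned_occupancy_trend(ids, sig, fc, 7)
  expect_equal(tr7$n_genes, c(rep(15, 5), rep(14, 2)))
  o <- sample.int(n)
  tr7b <- binned_occupancy_trend(ids[o], sig[o], fc[o], 7)
  expect_equal(tr7, tr7b)
})

test_that("z-scoring centers rows and averages duplicate probes first", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(z <- zscore_matrix(m), "zero-variance")
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  # duplicate probes: z of the probe mean
  probes <- rbind(c(1, 2, 3), c(3, 4, 5), c(10, 11, 12))
  z2 <- zscore_matrix(probes, gene_ids = c("g1", "g1", "g2"))
  expect_equal(unname(z2["g1", ]), unname(zscore_matrix(rbind(g1 = c(2, 3, 4),
                                                              x = c(0, 1, 7)))["g1", ]))
  expect_equal(nrow(z2), 2)
})

test_that("top down-regulated selection feeds the heatmap matrix", {
  set.seed(4)
  mat <- matrix(rlnorm(40), 10, 4,
                dimnames = list(sprintf("probe%02d", 1:10), NULL))
  genes <- rep(sprintf("g%d", 1:5), each = 2)
  lfc <- c(g1 = -3, g2 = -2, g3 = 0.5, g4 = -2.5, g5 = 1)
  fdr <- c(g1 = 0.01, g2 = 0.2, g3 = 0.01, g4 = 0.01, g5 = 0.01)
  z <- top_regulated_zscores(mat, genes, lfc, fdr, top_k = 2)
  expect_equal(rownames(z), c("g1", "g4")) # g2 fails the FDR gate
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
})

test_that("occupancy matrix bins windows and sorts rows deterministically", {
  tr <- signal_track(list(chr1 = rep(3, 20000)))
  anchors <- data.frame(chrom = "chr1", pos = c(6000L, 12000L))
  om <- occupancy_matrix(anchors, tr, flank = 1000, n_cols = 10)
  expect_true(all(abs(om$matrix - 3) < 1e-12))
  expect_equal(om$meta, rep(3, 10))
  # single planted bump at the anchor peaks centrally in the meta profile
  vals <- numeric(20000); vals[9951:10050] <- 5
  tr2 <- signal_track(list(chr1 = vals))
  om2 <- occupancy_matrix(data.frame(chrom = "chr1", pos = 10000L), tr2,
                          flank = 1000, n_cols = 20)
  expect_equal(which.max(om2$meta + rev(om2$meta)), 10)
  expect_gt(mean(om2$meta[10:11]), mean(om2$meta[c(1:3, 18:20)]))
  # permuting anchors leaves the sorted matrix unchanged
  set.seed(5)
  vals3 <- runif(20000)
  tr3 <- signal_track(list(chr1 = vals3))
  a3 <- data.frame(chrom = "chr1", pos = sample(2000:18000, 8))
  m_a <- occupancy_matrix(a3, tr3, flank = 500, n_cols = 5)$matrix
  m_b <- occupancy_matrix(a3[sample.int(8), , drop = FALSE], tr3,
                          flank = 500, n_cols = 5)$matrix
  expect_equal(m_a, m_b)
  # fully out-of-bounds window gives a zero row
  om4 <- occupancy_matrix(data.frame(chrom = "chr9", pos = 100L), tr3,
                          flank = 500, n_cols = 5)
  expect_equal(om4$matrix[1, ], rep(0, 5))
})

test_that("class-wise Mann-Whitney tests behave at the boundaries", {
  # exact two-sided p for A=[1,2] vs B=[3,4] is 2/6
  r <- signal_by_class_test(c(1, 2, 3, 4), c("down", "down", "ns", "ns"))
  expect_warning(signal_by_class_test(c(1, 2), c("down", "ns")), "empty group")
  dn <- r[r$group_a == "down" & r$group_b == "ns", ]
  expect_equal(dn$U, 0)
  expect_equal(dn$p_value, 1 / 3, tolerance = 1e-12)
  # identical groups: p near 1
  set.seed(6)
  x <- rep(c(1, 2, 3), 10)
  r2 <- signal_by_class_test(c(x, x), rep(c("down", "ns"), each = 30))
  expect_gt(r2$p_value[r2$group_a == "down" & r2$group_b == "ns"], 0.9)
  # planted shift is detected decisively
  sig <- c(rnorm(500, 5), rnorm(500, 0))
  cls <- rep(c("down", "up"), each = 500)
  r3 <- signal_by_class_test(c(sig, rnorm(10)), c(cls, rep("ns", 10)))
  expect_lt(r3$p_value[r3$group_a == "down" & r3$group_b == "up"], 1e-6)
})

test_that("log2 fold change uses the stated pseudocount", {
  expr <- data.frame(gene_id = "g", control_1 = 2, control_2 = 2,
                     ko_1 = 1, ko_2 = 1)
  expect_equal(expression_log2fc(expr, c("ko_1", "ko_2"),
                                 c("control_1", "control_2")),
               log2(1.01 / 2.01))
})
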