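# The seeded generator: determinism, planted-structure bookkeeping,
# file round-trips and noiseless recovery limits.

test_that("the same seed reproduces the bundle byte for byte", {
  cfg <- small_sim_config(seed = 99)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulate_epigenome(cfg, out_dir = d1)
  simulate_epigenome(cfg, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 10)
  expect_equal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("boundary and infeasible configs are handled", {
  b <- simulate_epigenome(small_sim_config(seed = 3,
                                           promoter_fraction_tf_a = 1.0))
  d <- distances_to_nearest_tss(b$peaks_tfa, b$genes)
  expect_true(all(d <= 2000))
  expect_error(
    simulate_epigenome(sim_config(seed = 1, n_genes = 100,
                                  n_peaks_tf_a = 400,
                                  promoter_fraction_tf_a = 1)),
    "infeasible")
})

test_that("planted TSS-proximal fractions are recovered within tolerance", {
  b <- simulate_epigenome(sim_config(seed = 2, n_peaks_tf_a = 2000,
                                     n_peaks_tf_b = 2000))
  d_a <- distances_to_nearest_tss(b$peaks_tfa, b$genes)
  d_b <- distances_to_nearest_tss(b$peaks_tfb, b$genes)
  expect_lt(abs(mean(d_a <= 5000) - 0.70), 0.03)
  expect_lt(abs(mean(d_b <= 5000) - 0.40), 0.03)
})

test_that("emitted files round-trip through the package readers", {
  d <- file.path(tempdir(), "sim_rt")
  b <- simulate_epigenome(small_sim_config(seed = 55), out_dir = d)
  genes <- read_tss_table(file.path(d, "tss.tsv"))
  expect_equal(genes, b$genes)
  pk <- read_peaks(file.path(d, "tfa_peaks.narrowPeak"))
  expect_equal(pk$summit, b$peaks_tfa$summit)
  expect_equal(pk$auc, b$peaks_tfa$auc, tolerance = 1e-6)
  expr <- read_expression_table(file.path(d, "expression.tsv"))
  expect_equal(expr$gene_id, b$expression$gene_id)
  expect_equal(expr$control_1, b$expression$control_1, tolerance = 1e-6)
  mh <- read_motif_hits(file.path(d, "motif_hits.tsv"))
  expect_equal(unname(mh$hits), unname(b$motif$hits))
  expect_equal(mh$anchors$anchor_tfa, b$motif$anchors$anchor_tfa)
  # the written ChIP track reproduces the planted peak AUCs
  lens <- setNames(rep(b$config$chrom_length, b$config$n_chromosomes),
                   sprintf("chr%d", seq_len(b$config$n_chromosomes)))
  tr <- read_bedgraph(file.path(d, "tfa.bedGraph"), chrom_lengths = lens)
  got <- peaks_with_auc(b$peaks_tfa[1:20, ], tr)
  expect_equal(got$auc, b$peaks_tfa$auc[1:20], tolerance = 1e-4)
  unlink(d, recursive = TRUE)
})

test_that("the noiseless planted trend is perfectly monotone", {
  b <- simulate_epigenome(small_sim_config(seed = 61, noise_sd_log2fc = 0))
  tg <- b$truth$genes
  bound <- tg$bound_tfa
  tr <- binned_occupancy_trend(tg$gene_id[bound],
                               tg$promoter_signal_true[bound],
                               tg$log2fc_true[bound], n_bins = 10)
  expect_equal(cor(tr$median_signal, tr$median_log2fc, method = "spearman"),
               -1)
})

test_that("a zero-effect generator plants no occupancy-expression link", {
  # with beta = 0 and no planted classes, bound and unbound genes show the
  # same fold-change distribution in most seeded runs
  pvals <- vapply(1:30, function(s) {
    b <- simulate_epigenome(small_sim_config(seed = 1000 + s, effect_beta = 0,
                                             n_direct_down = 0,
                                             n_indirect_up = 0))
    expr <- filter_expressed(b$expression)
    lfc <- expression_log2fc(expr, c("ko_1", "ko_2"),
                             c("control_1", "control_2"))
    bound <- b$truth$genes$bound_tfa[match(expr$gene_id,
                                           b$truth$genes$gene_id)]
    suppressWarnings(wilcox.test(lfc[bound], lfc[!bound])$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("ground truth is internally consistent with the emitted tables", {
  b <- simulate_epigenome(small_sim_config(seed = 77))
  tg <- b$truth$genes
  expect_equal(tg$gene_id, b$genes$gene_id)
  # planted statuses: direct-down genes are bound, indirect-up are not
  expect_true(all(tg$bound_tfa[tg$status == "direct_down"]))
  expect_true(!any(tg$bound_tfa[tg$status == "indirect_up"]))
  # promoter signal truth equals the pipeline's own quantification
  got <- gene_promoter_signal(b$genes, b$peaks_tfa)
  expect_equal(got, tg$promoter_signal_true, tolerance = 1e-9)
  # every proximal peak's bound gene exists
  pa <- b$truth$peaks_tfa
  expect_true(all(pa$bound_gene[pa$planted_class == "proximal"] %in%
                    b$genes$gene_id))
})
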