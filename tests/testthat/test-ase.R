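test_that("fold difference is symmetric, >= 1, and classed by thresholds", {
  fd <- compute_fold_difference(c(50, 30, 100, 45, 18), c(50, 10, 10, 30, 12))
  expect_equal(fd$fold, c(1, 3, 10, 1.5, 1.5))
  expect_equal(as.character(fd$ai_class),
               c("equal", "ai", "excluded", "equal", "equal"))
  # symmetry in the arguments
  expect_equal(compute_fold_difference(30, 10)$fold,
               compute_fold_difference(10, 30)$fold)
  # classes are exhaustive and exclusive for non-dropped records
  set.seed(2)
  a <- rpois(500, 40); b <- rpois(500, 40)
  fd2 <- compute_fold_difference(a, b)
  expect_true(all(fd2$fold >= 1, na.rm = TRUE))
  expect_false(anyNA(fd2$ai_class[!is.na(fd2$fold)]))
  # zero handling: pseudocount by default, drop on request
  expect_equal(compute_fold_difference(0, 9)$fold, 10)  # (0+1, 9+1)
  expect_true(is.na(compute_fold_difference(0, 9, zero_policy = "drop")$fold))
  expect_true(is.na(compute_fold_difference(0, 0)$fold))
  expect_error(compute_fold_difference(-1, 5), "negative")
})

test_that("transcript filtering keeps the best-covered isoform below the p cut", {
  tx <- data.frame(
    transcript = c("a.1", "a.2", "b.1", "c.1", "d.1", "d.2"),
    gene = c("a", "a", "b", "c", "d", "d"),
    assoc_p = c(1e-7, 1e-8, 1e-5, 1e-6, 0.2, 1e-9),
    total_counts = c(500, 200, 900, 100, 800, 300))
  kept <- filter_transcripts(tx)
  # gene a: both isoforms pass, 500-count one kept; gene b: p = 1e-5 exactly
  # is dropped (strict inequality); gene d: only the passing isoform counts
  expect_setequal(kept, c("a.1", "c.1", "d.2"))
  expect_equal(filter_transcripts(tx[tx$gene == "b", ]), character(0))
})

test_that("vicinity windows are closed at gene end + window", {
  txs <- data.frame(transcript = "t1", chrom = "chr1",
                    start = 50000, end = 60000)
  v <- data.frame(chrom = "chr1",
                  pos = c(30000, 30001, 80000, 80001, 55000),
                  class = factor(c("rare", "rare", "novel", "novel", "common"),
                                 levels = c("common", "rare", "novel")))
  cnt <- vicinity_variant_counts(txs, v, window = 20000)
  # pos 30001 is exactly start - 20000 + 1 (1-based): included;
  # pos 80000 is exactly end + 20000: included; 30000 and 80001 are out
  expect_equal(cnt$n_rare, 1)
  expect_equal(cnt$n_novel, 1)
  expect_equal(cnt$n_common, 1)
  expect_equal(cnt$n_rare_novel, 2)
  # no variants in range: zero vector
  far <- data.frame(chrom = "chr2", pos = 1, class = factor("rare",
                    levels = levels(v$class)))
  cnt2 <- vicinity_variant_counts(txs, far, window = 20000)
  expect_equal(unlist(cnt2[, -1], use.names = FALSE), c(0, 0, 0, 0))
  # oracle scan on random variants
  set.seed(9)
  vr <- data.frame(chrom = "chr1", pos = sample(1e5, 50),
                   class = factor(sample(c("common", "rare", "novel"), 50,
                                         TRUE),
                                  levels = c("common", "rare", "novel")))
  cnt3 <- vicinity_variant_counts(txs, vr, window = 20000)
  sel <- vr$pos - 1 >= 30000 & vr$pos - 1 < 80000
  expect_equal(cnt3$n_common, sum(sel & vr$class == "common"))
  expect_equal(cnt3$n_rare_novel, sum(sel & vr$class != "common"))
})

test_that("SNP-count adjustment is exact identity and hand arithmetic", {
  fold <- c(1.2, 1.7, 2.5, 3.2, 4, 10, 2.1, 1.4, 3.6, 2.9)
  snps <- rep(4, 10)
  hv <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  res <- adjusted_ai_proportions(fold, snps, hv, levels = c(1.5, 2, 3))
  # identical SNP counts: adjusted equals raw everywhere
  expect_equal(res$raw, res$adjusted)
  # hand arithmetic at level 2: transcripts with fold in [2, 9]
  sel <- fold >= 2 & fold <= 9
  expect_equal(res$raw[res$level == 2], mean(hv[sel]))
  # unequal SNP counts rescale by relative mean
  snps2 <- c(2, 2, 8, 8, 8, 2, 8, 2, 8, 8)
  res2 <- adjusted_ai_proportions(fold, snps2, hv, levels = c(2))
  grand <- mean(snps2[fold <= 9])
  expect_equal(res2$adjusted, mean(hv[sel]) * grand / mean(snps2[sel]))
  expect_warning(adjusted_ai_proportions(fold, snps, hv, levels = 8.5),
                 "no transcripts")
})

test_that("promoter-DHS correlation matches closed-form Pearson", {
  g <- bin_grid(c(chr1 = 5000), 100)
  tx <- data.frame(transcript = "t", chrom = "chr1", tss = 2050,
                   strand = "+")
  set.seed(12)
  sig <- matrix(runif(4 * 50), nrow = 4)
  # a bin identical to the promoter mean correlates at exactly 1
  prom_bins <- pos_to_bin(g, "chr1", 2049 - 500):pos_to_bin(g, "chr1", 2049 + 500)
  sig[, 40] <- rowMeans(sig[, prom_bins])
  links <- correlate_promoter_dhs(sig, g, tx, max_dist = 2000)
  expect_equal(links$r[links$bin_id == 40], 1)
  # arbitrary bin matches cor() by hand
  expect_equal(links$r[links$bin_id == 3],
               cor(rowMeans(sig[, prom_bins]), sig[, 3]))
  # promoter bins themselves are not linked
  expect_false(any(links$bin_id %in% prom_bins))
  expect_error(correlate_promoter_dhs(sig[1:2, ], g, tx), "3 datasets")
  # independent signal rarely exceeds |r| = 0.5 with 20 datasets
  g2 <- bin_grid(c(chr1 = 40000), 100)
  tx2 <- data.frame(transcript = "t", chrom = "chr1", tss = 20050,
                    strand = "+")
  set.seed(3)
  sig20 <- matrix(runif(20 * n_bins(g2)), nrow = 20)
  l20 <- correlate_promoter_dhs(sig20, g2, tx2, max_dist = 15000)
  expect_gt(nrow(l20), 250)
  expect_lt(mean(abs(l20$r) >= 0.5), 0.06)
})

test_that("AI enrichment is 1 on identical sets and matches hand ratios", {
  all_tx <- paste0("t", 1:20)
  has <- stats::setNames(rep(c(TRUE, FALSE), 10), all_tx)
  expect_equal(ai_enrichment(all_tx, all_tx, has), 1)
  ai <- all_tx[1:4]   # has = TRUE, FALSE, TRUE, FALSE
  expect_equal(ai_enrichment(ai, all_tx, has), (2 / 4) / (10 / 20))
  expect_error(ai_enrichment(character(0), all_tx, has), "non-empty")
  expect_true(is.na(ai_enrichment(ai, all_tx, stats::setNames(
    rep(FALSE, 20), all_tx))))
})

test_that("homozygous stratification keeps 0/0 and 1/1 records only", {
  rec <- data.frame(transcript = rep(c("t1", "t2", "t3"), each = 2),
                    individual = rep(c("i1", "i2"), 3))
  gt <- data.frame(transcript = c("t1", "t1", "t2", "t2"),
                   individual = c("i1", "i2", "i1", "i2"),
                   gt = c("0/0", "0/1", "1/1", "0/1"))
  hom <- stratify_homozygous(rec, gt)
  expect_equal(nrow(hom), 2)
  expect_equal(paste(hom$transcript, hom$individual), c("t1 i1", "t2 i1"))
  # transcripts without an eSNP annotation (t3) are excluded from homAI
  expect_false("t3" %in% hom$transcript)
  all_het <- transform(gt, gt = "0/1")
  expect_warning(out <- stratify_homozygous(rec, all_het), "no homozygous")
  expect_equal(nrow(out), 0)
})

test_that("dose-response strata match hand arithmetic", {
  ai <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  count <- c(0, 0, 0, 1, 1, 2, 4, 5)
  dr <- count_dose_response(ai, count, max_count = 3)
  expect_equal(dr$table$count, c(0, 1, 2, 3))
  expect_equal(dr$table$raw, c(1 / 3, 1, 0, 1))
  expect_true(dr$trend_p >= 0 && dr$trend_p <= 1)
})

test_that("TSS-distance profile equals the hand ratio in a single window", {
  ai <- data.frame(chrom = "chr1", tss = 100000, strand = "+")
  all_tx <- rbind(ai, data.frame(chrom = "chr1", tss = 500000, strand = "+"))
  v <- data.frame(chrom = "chr1", pos = c(100005, 100007, 500003))
  prof <- tss_distance_enrichment(ai, all_tx, v, window = 1000, step = 1000,
                                  max_dist = 0)
  # near the AI transcript: 2 variants / 1 transcript; background:
  # 3 variants / 2 transcripts
  expect_equal(prof$fold, (2 / 1) / (3 / 2))
  # minus-strand transcripts flip the sign of the distance
  d <- variant_tss_distances(
    data.frame(chrom = "chr1", tss = 1000, strand = "-"),
    data.frame(chrom = "chr1", pos = 1400))
  expect_equal(d, -400)
})

test_that("variance explained is 1 for a noise-free response and ~0 under the null", {
  count <- rpois(200, 1)
  expect_equal(residual_variance_explained(2^(0.2 * count + 1), count), 1)
  set.seed(8)
  r2_null <- residual_variance_explained(2^abs(rnorm(5000, 0, 0.5)),
                                         rpois(5000, 1))
  expect_lt(r2_null, 0.01)
  expect_error(residual_variance_explained(c(1, 2), c(0, 1)), "10 records")
  expect_true(is.na(residual_variance_explained(rep(2, 50), rpois(50, 1))))
})
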