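test_that("genome generation is deterministic, length-exact, ACGT-only", {
  g <- make_genome(c(chrT = 100000), seed = 1)
  expect_equal(Biostrings::width(g), 100000)
  expect_equal(sort(unique(strsplit(as.character(g[[1]]), "")[[1]])),
               c("A", "C", "G", "T"))
  expect_identical(as.character(g), as.character(make_genome(c(chrT = 1e5),
                                                             seed = 1)))
  expect_false(identical(as.character(g),
                         as.character(make_genome(c(chrT = 1e5), seed = 2))))
  expect_error(make_genome(c(chrT = -5)), "positive")
})

test_that("shared peaks show elevated counts in all carrying cell types", {
  sim <- simulate_dhs_experiments(c(chrA = 1e5), c("X", "Y"), c(X = 2, Y = 2),
                                  peaks_per_level = c(2, 2), seed = 3)
  shared <- sim$truth$peaks[sim$truth$peaks$level == 2, ][1, ]
  peak_bins <- shared$start_bin:shared$end_bin
  bg <- setdiff(seq_len(n_bins(sim$grid)),
                unlist(mapply(seq, sim$truth$peaks$start_bin,
                              sim$truth$peaks$end_bin)))
  for (s in seq_len(ncol(sim$counts))) {
    expect_gt(mean(sim$counts[peak_bins, s]), mean(sim$counts[bg, s]) + 10)
  }
  expect_error(simulate_dhs_experiments(c(chrA = 1e5), "X", c(X = 1),
                                        peaks_per_level = 1, depth = 0),
               "depth")
  expect_error(simulate_dhs_experiments(c(chrA = 1e5), "X", c(X = 0),
                                        peaks_per_level = 1), "replicate")
  # determinism
  sim2 <- simulate_dhs_experiments(c(chrA = 1e5), c("X", "Y"),
                                   c(X = 2, Y = 2),
                                   peaks_per_level = c(2, 2), seed = 3)
  expect_identical(sim$counts, sim2$counts)
  expect_identical(sim$truth$peaks, sim2$truth$peaks)
})

test_that("planted consensus peaks are recovered by the design across seeds", {
  hits <- vapply(1:20, function(i) {
    recover_peak_architecture(n_cell_types = 3, replicates = 3,
                              peaks_per_level = c(2, 2, 2), seed = i)$exact
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("background-only simulation puts nothing in the truth set", {
  sim <- simulate_dhs_experiments(c(chrA = 5e4), "X", c(X = 1),
                                  peaks_per_level = 0, seed = 4)
  expect_equal(nrow(sim$truth$peaks), 0)
  top <- select_top_bins(bin_and_normalize(sim$counts[, 1], sim$grid), 50)
  expect_equal(length(intersect(top, integer(0))), 0)
})

test_that("variant simulation honours its contracts and truth is complete", {
  g <- bin_grid(c(chrA = 1e5))
  pan <- synthetic_panel(g, bins_per_level = c(50, 50, 50), seed = 2)
  expect_error(simulate_variants(pan, enrichment_fold = 0.5), ">= 1")
  sim <- simulate_variants(pan, enrichment_fold = 1, n_per_level = 100,
                           n_samples = 8, qc_violation_frac = 0.1, seed = 5)
  # truth completeness: every emitted variant has a planted class and level
  expect_setequal(names(sim$truth$classes), sim$variants$variant_id)
  expect_setequal(names(sim$truth$levels), sim$variants$variant_id)
  # planted QC violations are removed by the filter, exactly
  qc <- qc_filter(sim$variants, sim$genotypes)
  expect_setequal(setdiff(sim$variants$variant_id, qc$variants$variant_id),
                  sim$truth$qc_violations)
  # classification recovers the planted classes via the frequency reference
  cls <- classify_frequency(sim$variants, sim$freq_ref)
  expect_equal(as.character(cls), unname(sim$truth$classes))
  # every common/rare variant appears in the reference; novel never does
  key <- paste(sim$variants$chrom, sim$variants$pos)
  in_ref <- key %in% paste(sim$freq_ref$chrom, sim$freq_ref$pos)
  expect_equal(in_ref, unname(sim$truth$classes != "novel"))
  # determinism
  sim2 <- simulate_variants(pan, enrichment_fold = 1, n_per_level = 100,
                            n_samples = 8, qc_violation_frac = 0.1, seed = 5)
  expect_identical(sim$variants, sim2$variants)
  expect_identical(sim$genotypes, sim2$genotypes)
  # sites-only mode emits the identical variant table
  sim3 <- simulate_variants(pan, enrichment_fold = 1, n_per_level = 100,
                            n_samples = 8, with_genotypes = FALSE, seed = 5)
  expect_identical(sim$variants, sim3$variants)
})

test_that("an all-common frequency spectrum yields no rare or novel calls", {
  g <- bin_grid(c(chrA = 2e4))
  v <- data.frame(chrom = "chrA", pos = seq(10, 1000, by = 10))
  v$ref <- "A"; v$alt <- "G"
  ref <- transform(v, af = 0.05)
  cls <- classify_frequency(v, ref)
  expect_true(all(cls == "common"))
})

test_that("planted motif events classify as planted; neutral-only stays silent", {
  pwms <- default_pwm_library()
  sim <- simulate_motif_variants(pwms, n_create = 3, n_disrupt = 3,
                                 n_neutral = 3, seed = 6)
  alpha <- bonferroni_alpha(0.05, 100)
  res <- classify_motif_impact(sim$variants, sim$genome, pwms, alpha)
  ev <- sim$truth$events
  created <- ev$variant_id[ev$event == "created"][1]
  pwm_id <- ev$pwm_id[ev$variant_id == created]
  expect_equal(res$calls$verdict[res$calls$variant_id == created &
                                   res$calls$pwm == pwm_id], "created")
  # neutral-only simulations make no calls at a stringent alpha
  silent <- vapply(1:10, function(i) {
    s <- simulate_motif_variants(pwms, 0, 0, 20, seed = 100 + i)
    r <- classify_motif_impact(s$variants, s$genome, pwms, alpha = 1e-7)
    all(r$calls$verdict == "none")
  }, logical(1))
  expect_gte(mean(silent), 0.95)
  expect_error(simulate_motif_variants(pwms, 1, 1, 1, flank = 2), "window")
})

test_that("ASE simulation is deterministic and symmetric at zero effect", {
  expect_error(simulate_ase(overdispersion = -1), "overdispersion")
  sim <- simulate_ase(n_transcripts = 100, n_individuals = 2,
                      effect_size = 0.8, seed = 7)
  sim2 <- simulate_ase(n_transcripts = 100, n_individuals = 2,
                       effect_size = 0.8, seed = 7)
  expect_identical(sim$records, sim2$records)
  # a record with equal counts folds to exactly 1 downstream
  expect_equal(compute_fold_difference(50, 50)$fold, 1)
  # planted effect produces AI enrichment among carriers across seeds
  hit <- vapply(1:20, function(i) {
    s <- simulate_ase(n_transcripts = 300, effect_size = 1, seed = 200 + i)
    fd <- compute_fold_difference(s$records$count_a, s$records$count_b)
    keep <- !is.na(fd$fold) & fd$ai_class != "excluded"
    ai <- fd$ai_class[keep] == "ai"
    carrier <- s$records$rare_count[keep] > 0
    mean(ai[carrier]) > mean(ai[!carrier])
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("truth objects survive a JSON round trip losslessly", {
  g <- bin_grid(c(chrA = 1e5))
  pan <- synthetic_panel(g, c(30, 30), seed = 3)
  sim <- simulate_variants(pan, n_per_level = 50, with_genotypes = FALSE,
                           seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$enrichment_fold, sim$truth$enrichment_fold)
  expect_equal(back$classes, sim$truth$classes)
  expect_equal(back$levels, sim$truth$levels)
})

test_that("synthetic panels realize the requested sharing histogram", {
  g <- bin_grid(c(chrA = 2e5))
  pan <- synthetic_panel(g, bins_per_level = c(10, 20, 30, 5), seed = 1)
  expect_equal(unname(table(pan$bins$sharing)), table(rep(1:4, c(10, 20, 30, 5))),
               ignore_attr = TRUE)
})
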