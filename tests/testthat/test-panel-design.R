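test_that("normalization divides by total reads and conserves mass", {
  g <- toy_grid()
  tr <- bin_and_normalize(c(10, 30, 60, rep(0, 13)), g)
  expect_equal(tr$values[1:3], c(0.1, 0.3, 0.6))
  # all-equal counts give all-equal signals
  tr2 <- bin_and_normalize(rep(7, 16), g)
  expect_true(all(abs(tr2$values - 1 / 16) < 1e-12))
  # random counts: signal sums to 1
  set.seed(1)
  for (i in 1:5) {
    tr3 <- bin_and_normalize(rpois(16, 20) + 1, g)
    expect_lt(abs(sum(tr3$values) - 1), 1e-12)
  }
  expect_error(bin_and_normalize(rep(0, 16), g), "zero")
})

test_that("bedGraph records are apportioned to bins by overlap fraction", {
  g <- toy_grid()
  tr <- bin_and_normalize(
    data.frame(chrom = "chr1", start = 50, end = 150, score = 10), g)
  expect_equal(tr$values[1], 0.5)
  expect_equal(tr$values[2], 0.5)
  expect_error(
    bin_and_normalize(data.frame(chrom = "chrNope", start = 0, end = 10,
                                 score = 1), g),
    "chrNope")
  expect_error(
    bin_and_normalize(data.frame(chrom = "chr1", start = 10, end = 10,
                                 score = 1), g),
    "malformed")
})

test_that("top-bin selection is a deterministic rank cut with genomic ties", {
  s <- c(b1 = 0.5, b2 = 0.3, b3 = 0.2, rep(0, 13))
  expect_equal(as.integer(select_top_bins(s, 2)), c(1L, 2L))
  # tie at the boundary: earlier genomic bin wins
  s2 <- c(0.5, 0.2, 0.2, rep(0, 13))
  expect_equal(as.integer(select_top_bins(s2, 2)), c(1L, 2L))
  expect_warning(out <- select_top_bins(s2, 20), "all bins")
  expect_equal(length(out), 16)
  # oracle: full sort with the same tie rule, random tracks
  set.seed(42)
  for (i in 1:10) {
    v <- sample(rpois(200, 3)) / 100
    n_top <- sample(1:200, 1)
    df <- data.frame(bin = seq_along(v), v = v)
    oracle <- df[order(-df$v, df$bin), "bin"][seq_len(n_top)]
    expect_equal(as.integer(select_top_bins(v, n_top)), oracle)
  }
})

test_that("consensus follows the 50% / both / single-sample rules", {
  expect_equal(consensus_bins(list(c(1, 2, 3), c(2, 3, 4))), c(2L, 3L))
  expect_equal(consensus_bins(list(c(9, 4, 7))), c(4L, 7L, 9L))
  expect_error(consensus_bins(list()), "no ranked sets")
  # m = 3: exhaustively check every membership pattern of one bin
  for (pattern in 1:7) {
    present <- as.logical(bitwAnd(pattern, c(1, 2, 4)))
    sets <- lapply(present, function(p) if (p) c(99L, 1L) else c(1L, 2L))
    got <- 99 %in% consensus_bins(sets)
    expect_equal(got, sum(present) >= 2)
  }
})

test_that("rank-block filtering keeps concordant strata", {
  a <- 1:8; b <- c(1:4, 9:12)  # stratum 1 identical, stratum 2 disjoint
  res <- filter_rank_blocks(list(a, b), block_size = 4)
  expect_equal(res$retained, c(TRUE, FALSE))
  expect_equal(res$overlap, c(1, 0))
  expect_equal(res$sets[[1]], 1:4)
  # single sample: everything retained
  res1 <- filter_rank_blocks(list(a), block_size = 4)
  expect_equal(res1$retained, c(TRUE, TRUE))
  expect_error(filter_rank_blocks(list(1:3), block_size = 4), "full block")
  # 3 samples: mean pairwise overlap equals the brute-force computation
  set.seed(7)
  for (i in 1:10) {
    sets <- lapply(1:3, function(s) sample(30, 12))
    res <- filter_rank_blocks(sets, block_size = 4, min_overlap = 0.5)
    for (j in 1:3) {
      idx <- ((j - 1) * 4 + 1):(j * 4)
      ov <- c()
      for (x in 1:2) for (y in (x + 1):3)
        ov <- c(ov, length(intersect(sets[[x]][idx], sets[[y]][idx])) / 4)
      expect_equal(res$overlap[j], mean(ov))
      expect_equal(res$retained[j], mean(ov) >= 0.5)
    }
  }
})

test_that("exome subtraction removes bins at >= 50% union overlap", {
  g <- toy_grid()
  # 50 bp overlap: removed; 49 bp: kept
  ex50 <- data.frame(chrom = "chr1", start = 0, end = 50)
  ex49 <- data.frame(chrom = "chr1", start = 0, end = 49)
  expect_equal(subtract_exome(1:2, g, ex50), 2L)
  expect_equal(subtract_exome(1:2, g, ex49), c(1L, 2L))
  # overlapping exome records are unioned: [0,60) + [40,80) covers 80 bp
  ex_union <- data.frame(chrom = "chr1", start = c(0, 40), end = c(60, 80))
  expect_equal(subtract_exome(1:2, g, ex_union), 2L)
  expect_error(subtract_exome(1:2, g,
                              data.frame(chrom = "chr1", start = 10, end = 10)),
               "line 1")
})

test_that("panel assembly merges adjacent bins and counts sharing", {
  g <- toy_grid()
  pan <- build_panel(list(X = c(1, 2), Y = c(2, 5)), g)
  expect_equal(pan$bins$bin_id, c(1L, 2L, 5L))
  expect_equal(pan$bins$sharing, c(1L, 2L, 1L))
  # bins 1 and 2 merge into one interval [0, 200)
  expect_equal(length(pan$intervals), 2)
  expect_equal(GenomicRanges::width(pan$intervals), c(200, 100))
  expect_equal(pan$total_target_bp, 300)
  expect_error(build_panel(list(), g), "at least one")
})

test_that("raising min_overlap never retains more strata; raising min_frac never shrinks the panel", {
  set.seed(11)
  sets <- lapply(1:3, function(s) sample(40, 16))
  kept <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(mo)
    sum(filter_rank_blocks(sets, 4, mo)$retained), numeric(1))
  expect_true(all(diff(kept) <= 0))
  g <- toy_grid()
  ex <- data.frame(chrom = "chr1", start = c(0, 250), end = c(70, 430))
  sizes <- vapply(c(0.2, 0.5, 0.8, 1.0), function(mf)
    length(subtract_exome(1:10, g, ex, min_frac = mf)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("full design equals the naive set-operation reference", {
  set.seed(23)
  for (rep in 1:3) {
    grid <- bin_grid(c(cA = 20000, cB = 10000), 100)  # 300 bins
    cell_type <- c("T", "T", "T", "B", "B", "M")
    counts <- sapply(seq_along(cell_type), function(s)
      rpois(n_bins(grid), 2) + rbinom(n_bins(grid), 20, 0.2))
    exome <- data.frame(chrom = "cA",
                        start = sort(sample(seq(0, 19000, 500), 6)))
    exome$end <- exome$start + sample(c(60, 120, 300), 6, replace = TRUE)
    tracks <- lapply(seq_along(cell_type), function(s)
      bin_and_normalize(counts[, s], grid, cell_type = cell_type[s]))
    pan <- design_panel(tracks, grid, n_top = 60, block_size = 20,
                        min_overlap = 0.5, exome = exome)
    ref <- naive_design(counts, cell_type, grid, n_top = 60,
                        block_size = 20, min_overlap = 0.5, exome = exome)
    expect_equal(pan$bins$bin_id, ref$bin_id)
    expect_equal(pan$bins$sharing, ref$sharing)
  }
})

test_that("surviving bins are drawn from every contributing sample's top set", {
  set.seed(5)
  grid <- bin_grid(c(cA = 10000), 100)
  counts <- sapply(1:3, function(s) rpois(100, 3))
  tracks <- lapply(1:3, function(s)
    bin_and_normalize(counts[, s], grid, cell_type = "T"))
  pan <- design_panel(tracks, grid, n_top = 30)
  tops <- lapply(tracks, select_top_bins, n_top = 30)
  # consensus needs ceiling(3/2) = 2 of 3 sets
  in_sets <- sapply(pan$bins$bin_id, function(b)
    sum(vapply(tops, function(s) b %in% s, logical(1))))
  expect_true(all(in_sets >= 2))
})
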