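mk_site <- function(id, mq = 60, ref = "A", alt = "G") {
  data.frame(variant_id = id, chrom = "chr1", pos = 100, ref = ref,
             alt = alt, mq = mq, stringsAsFactors = FALSE)
}
mk_call <- function(id, gt = "0/1", dp = 50, gq = 99, ab = 0.5) {
  data.frame(variant_id = id, sample = "S1", gt = gt, dp = dp, gq = gq,
             ad_ref = round(ab * dp), stringsAsFactors = FALSE)
}

test_that("QC rule table: thresholds are inclusive and balance is het-only", {
  cases <- list(
    list(call = mk_call("v", dp = 10, gq = 70, ab = 0.5), mq = 50, pass = TRUE),
    list(call = mk_call("v", dp = 9), mq = 60, pass = FALSE),
    list(call = mk_call("v", gq = 69), mq = 60, pass = FALSE),
    list(call = mk_call("v"), mq = 49, pass = FALSE),
    list(call = mk_call("v", ab = 0.95), mq = 60, pass = FALSE),
    list(call = mk_call("v", ab = 0.10), mq = 60, pass = TRUE),
    list(call = mk_call("v", ab = 0.90), mq = 60, pass = TRUE),
    # hom-alt with extreme balance passes: the balance rule is het-only
    list(call = mk_call("v", gt = "1/1", ab = 0.02), mq = 60, pass = TRUE),
    list(call = mk_call("v", gt = "0/0", ab = 1.0), mq = 60, pass = TRUE))
  for (cs in cases) {
    res <- qc_filter(mk_site("v", mq = cs$mq), cs$call)
    expect_equal(nrow(res$genotypes) == 1, cs$pass)
  }
  # missing required field fails that call and is logged
  bad <- mk_call("v"); bad$dp <- NA
  res <- qc_filter(mk_site("v"), bad)
  expect_equal(nrow(res$genotypes), 0)
  expect_match(res$rejections$reason, "missing")
})

test_that("indels are excluded and filtering is idempotent", {
  sites <- rbind(mk_site("snv"), mk_site("ins", ref = "A", alt = "AT"))
  calls <- rbind(mk_call("snv"), mk_call("ins"))
  res <- qc_filter(sites, calls)
  expect_equal(res$variants$variant_id, "snv")
  expect_true("indel" %in% res$rejections$reason)
  res2 <- qc_filter(res$variants, res$genotypes)
  expect_equal(res2$variants, res$variants)
  expect_equal(res2$genotypes, res$genotypes)
})

test_that("frequency classes follow MAF thresholds and allele matching", {
  ref <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40),
                    ref = c("A", "A", "A", "A"), alt = c("G", "G", "G", "G"),
                    af = c(0.05, 0.002, 0.995, 0.5))
  v <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40, 50, 20),
                  ref = "A", alt = c("G", "G", "G", "G", "G", "C"))
  cls <- classify_frequency(v, ref)
  # af 0.05 -> common; af 0.002 -> rare; af 0.995 folds to MAF 0.005 -> rare
  # af 0.5 -> common; absent -> novel; position match but different alt -> novel
  expect_equal(as.character(cls),
               c("common", "rare", "rare", "common", "novel", "novel"))
  # known-sites list without frequencies makes a variant rare, not novel
  ks <- data.frame(chrom = "chr1", pos = 50, ref = "A", alt = "G")
  cls2 <- classify_frequency(v, ref, known_sites = ks)
  expect_equal(as.character(cls2)[5], "rare")
  # classes partition every variant
  expect_false(anyNA(cls))
})

test_that("coding effects match exhaustive translate-and-compare on both strands", {
  w <- toy_coding_world()
  # plus-strand gene: every possible SNV in its CDS
  vars_p <- all_snvs_in(w$genome, "chrZ", 11, 10 + nchar(w$plus_cds))
  eff <- annotate_coding_effect(vars_p, w$cds, w$genome)
  oracle <- apply(vars_p, 1, function(r) {
    s <- w$plus_cds
    p <- as.integer(r["pos"]) - 10
    substring(s, p, p) <- r["alt"]
    aa0 <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(w$plus_cds))), "")[[1]]
    aa1 <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(s))), "")[[1]]
    i <- (p - 1) %/% 3 + 1
    if (aa0[i] == aa1[i]) "synonymous"
    else if (aa1[i] == "*" && aa0[i] != "*") "stop-gained"
    else "non-synonymous"
  })
  expect_equal(as.character(eff), unname(oracle))
  expect_true(all(c("synonymous", "non-synonymous", "stop-gained")
                  %in% eff))
  # minus-strand gene: one known case per effect
  m_start <- 10 + nchar(w$plus_cds) + 10  # 0-based CDS start on the genome
  gseq <- as.character(w$genome[[1]])
  vars_m <- all_snvs_in(w$genome, "chrZ", m_start + 1,
                        m_start + nchar(w$minus_cds))
  eff_m <- annotate_coding_effect(vars_m, w$cds, w$genome)
  oracle_m <- apply(vars_m, 1, function(r) {
    p_genome <- as.integer(r["pos"])
    cds <- revcomp_chr(substring(gseq, m_start + 1,
                                 m_start + nchar(w$minus_cds)))
    p_cds <- m_start + nchar(w$minus_cds) - p_genome + 1
    s <- cds
    substring(s, p_cds, p_cds) <- chartr("ACGT", "TGCA", r["alt"])
    aa0 <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds))), "")[[1]]
    aa1 <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(s))), "")[[1]]
    i <- (p_cds - 1) %/% 3 + 1
    if (aa0[i] == aa1[i]) "synonymous"
    else if (aa1[i] == "*" && aa0[i] != "*") "stop-gained"
    else "non-synonymous"
  })
  expect_equal(as.character(eff_m), unname(oracle_m))
  # outside any CDS: non-coding
  nc <- annotate_coding_effect(
    data.frame(chrom = "chrZ", pos = 3, ref = "A", alt = "G"), w$cds,
    w$genome)
  expect_equal(as.character(nc), "non-coding")
  # reference mismatch with the genome is rejected and logged
  bad <- data.frame(chrom = "chrZ", pos = 12, ref = "C", alt = "G")
  if (substring(gseq, 12, 12) == "C") bad$ref <- "G"
  effb <- annotate_coding_effect(bad, w$cds, w$genome)
  expect_true(is.na(effb[1]))
  expect_equal(attr(effb, "rejected"), 1L)
})

test_that("sharing levels match a naive point-in-interval lookup", {
  g <- toy_grid()
  pan <- build_panel(list(X = c(1, 2, 5), Y = c(2, 9), Z = c(2, 5)), g)
  set.seed(6)
  v <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                  pos = sample(540, 40))
  lev <- assign_dhs_sharing(v, pan)
  naive <- vapply(seq_len(nrow(v)), function(i) {
    iv <- bin_to_interval(g, pan$bins$bin_id)
    hit <- which(iv$chrom == v$chrom[i] & v$pos[i] - 1 >= iv$start &
                   v$pos[i] - 1 < iv$end)
    if (length(hit)) pan$bins$sharing[hit] else 0L
  }, integer(1))
  expect_equal(lev, naive)
  # a variant in a bin shared by all three cell types gets level 3
  iv2 <- bin_to_interval(g, 2)
  expect_equal(assign_dhs_sharing(
    data.frame(chrom = iv2$chrom, pos = iv2$start + 1), pan), 3L)
})

test_that("sharing-level folds equal hand ratios; identical ratios give slope 0", {
  cls <- factor(rep(c("common", "rare"), times = c(120, 60)),
                levels = c("common", "rare", "novel"))
  lvl <- c(rep(1:3, each = 40), rep(1:3, times = c(10, 20, 30)))
  enr <- sharing_level_enrichment(cls, lvl,
    class_sets = list(rare = "rare", rare_novel = c("rare", "novel")))
  rn <- enr$table[enr$table$class_set == "rare_novel", ]
  expect_equal(rn$fold, c((10 / 40) / 0.5, (20 / 40) / 0.5, (30 / 40) / 0.5))
  expect_equal(enr$fits$slope[enr$fits$class_set == "rare_novel"], 0.5)
  # identical class ratios at every level: folds 1, slope 0
  cls2 <- factor(rep(c("common", "rare"), times = c(90, 90)),
                 levels = c("common", "rare", "novel"))
  lvl2 <- rep(rep(1:3, each = 30), 2)
  enr2 <- sharing_level_enrichment(cls2, lvl2,
                                   class_sets = list(rare = "rare"))
  expect_true(all(abs(enr2$table$fold[enr2$table$class_set == "rare"] - 1)
                  < 1e-12))
  expect_equal(enr2$fits$slope[enr2$fits$class_set == "rare"], 0)
  expect_error(sharing_level_enrichment(cls[1:40], rep(1, 40)), "two")
})

test_that("class-label permutation centers the sharing slope at zero", {
  set.seed(31)
  cls <- factor(sample(rep(c("common", "rare"), times = c(300, 150))),
                levels = c("common", "rare", "novel"))
  lvl <- sample(1:5, 450, TRUE, prob = c(5, 4, 3, 2, 1))
  slopes <- vapply(1:200, function(i) {
    p <- sample(cls)
    enr <- sharing_level_enrichment(p, lvl, class_sets = list(rare = "rare"))
    enr$fits$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(200))
})

test_that("constraint proportions and contrasts match hand enumeration", {
  cls <- factor(c(rep("common", 6), rep("novel", 6)),
                levels = c("common", "rare", "novel"))
  score <- c(3, 3, 0, 0, 0, 0, 3, 3, 3, 3, 0, NA)
  res <- constraint_proportions(cls, score, thresholds = c(1, 2))
  p <- res$proportions
  expect_equal(p$prop[p$class == "common" & p$threshold == 1], 2 / 6)
  # missing scores count as below threshold but stay in the denominator
  expect_equal(p$prop[p$class == "novel" & p$threshold == 2], 4 / 6)
  ct <- res$contrasts
  hand <- fisher_enrichment(2, 4, 4, 2)
  expect_equal(ct$p_value[ct$class_a == "common" & ct$class_b == "novel" &
                            ct$threshold == 1], hand$p_value)
  # saturation and empty extremes
  sat <- constraint_proportions(cls, rep(3, 12), thresholds = c(1, 2))
  expect_true(all(sat$proportions$prop[sat$proportions$class
                                       %in% c("common", "novel")] == 1))
  none <- constraint_proportions(cls, rep(-5, 12), thresholds = c(1, 2))
  expect_true(all(none$proportions$prop[none$proportions$class
                                        %in% c("common", "novel")] == 0))
})

test_that("summary table accounting: total = coding + non-coding per class", {
  set.seed(13)
  n <- 200
  cls <- factor(sample(c("common", "rare", "novel"), n, TRUE),
                levels = c("common", "rare", "novel"))
  eff <- factor(sample(c("synonymous", "non-synonymous", "stop-gained",
                         "non-coding"), n, TRUE, prob = c(1, 1, 0.2, 4)),
                levels = c("synonymous", "non-synonymous", "stop-gained",
                           "non-coding"))
  sh <- sample(0:4, n, TRUE)
  tab <- variant_summary_table(cls, eff, sh)
  for (col in c("all", "common", "rare", "novel")) {
    expect_equal(tab[tab$category == "all", col],
                 tab[tab$category == "coding", col] +
                   tab[tab$category == "non-coding", col])
    expect_equal(tab[tab$category == "coding", col],
                 sum(tab[tab$category %in% c("non-synonymous", "synonymous",
                                             "stop-gained"), col]))
  }
  expect_equal(tab[tab$category == "all", "all"], n)
})
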