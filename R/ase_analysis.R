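#' Allelic fold difference and imbalance class
#'
#' Fold difference is the count of the more abundant allele divided by
#' the count of the less abundant one, so equal expression gives fold 1.
#' Classes: `equal` (fold <= 1.5), `intermediate` (1.5 < fold < 2),
#' `ai` (2 <= fold <= 9, allelic imbalance), `excluded` (fold > 9,
#' enriched for imprinting and artefacts; dropped from enrichment
#' denominators downstream). When either count is zero a pseudocount of
#' one is added to both alleles (`zero_policy = "drop"` removes the
#' record instead); records with both counts zero are always dropped.
#'
#' @param count_a,count_b Allele read counts (haplotype A and B).
#' @param zero_policy `"pseudocount"` (default) or `"drop"`.
#' @param equal_max,ai_min,ai_max Class thresholds (1.5, 2, 9).
#' @return data.frame with `fold` and `ai_class` (`NA` rows mark dropped
#'   records).
#' @export
compute_fold_difference <- function(count_a, count_b,
                                    zero_policy = c("pseudocount", "drop"),
                                    equal_max = 1.5, ai_min = 2, ai_max = 9) {
  zero_policy <- match.arg(zero_policy)
  a <- as.numeric(count_a); b <- as.numeric(count_b)
  if (any(a < 0 | b < 0, na.rm = TRUE)) stop("negative allele counts")
  drop <- (a == 0 & b == 0) | is.na(a) | is.na(b)
  zero <- (a == 0 | b == 0) & !drop
  if (zero_policy == "pseudocount") {
    a[zero] <- a[zero] + 1
    b[zero] <- b[zero] + 1
  } else {
    drop <- drop | zero
  }
  fold <- pmax(a, b) / pmin(a, b)
  fold[drop] <- NA_real_
  cls <- ifelse(fold <= equal_max, "equal",
         ifelse(fold < ai_min, "intermediate",
         ifelse(fold <= ai_max, "ai", "excluded")))
  data.frame(fold = fold,
             ai_class = factor(cls, levels = c("equal", "intermediate",
                                               "ai", "excluded")))
}

#' Keep significantly associated transcripts, one isoform per gene
#'
#' Retains transcripts with ASE association p-value strictly below the
#' threshold and, within each gene, the best-covered isoform.
#'
#' @param tx data.frame with `transcript`, `gene`, `assoc_p`,
#'   `total_counts` (normalized read counts used for isoform choice).
#' @param association_p_max Threshold (default 1e-5; boundary excluded).
#' @return Character vector of kept transcript ids.
#' @export
filter_transcripts <- function(tx, association_p_max = 1e-5) {
  keep <- tx[!is.na(tx$assoc_p) & tx$assoc_p < association_p_max, , drop = FALSE]
  if (!nrow(keep)) return(character(0))
  picked <- vapply(split(keep, keep$gene), function(d)
    d$transcript[which.max(d$total_counts)], character(1))
  unname(picked)
}

#' Variants in the vicinity of each transcript
#'
#' Counts variants per frequency class inside the closed vicinity window
#' `[gene start - window, gene end + window]`. An optional logical filter
#' (e.g. non-coding, in-DHS) restricts which variants are counted.
#'
#' @param transcripts data.frame with `transcript`, `chrom`, `start`,
#'   `end` (0-based half-open gene span).
#' @param variants data.frame with `chrom`, `pos` (1-based), `class`.
#' @param window Flank in bp (default 20,000).
#' @param variant_filter Optional logical vector over `variants` rows.
#' @return data.frame per transcript with `n_common`, `n_rare`,
#'   `n_novel`, `n_rare_novel`.
#' @export
vicinity_variant_counts <- function(transcripts, variants, window = 20000,
                                    variant_filter = NULL) {
  v <- variants
  if (!is.null(variant_filter)) v <- v[variant_filter, , drop = FALSE]
  pos0 <- v$pos - 1L
  out <- lapply(seq_len(nrow(transcripts)), function(i) {
    sel <- v$chrom == transcripts$chrom[i] &
      pos0 >= transcripts$start[i] - window &
      pos0 < transcripts$end[i] + window
    cl <- v$class[sel]
    data.frame(transcript = transcripts$transcript[i],
               n_common = sum(cl == "common"),
               n_rare = sum(cl == "rare"),
               n_novel = sum(cl == "novel"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$n_rare_novel <- res$n_rare + res$n_novel
  res
}

#' SNP-count-adjusted AI proportions across imbalance levels
#'
#' For each lower fold bound `level`, the raw proportion is the fraction
#' of transcripts with fold in `[level, upper]` that carry at least one
#' vicinity variant of the class. The adjustment rescales by the relative
#' mean number of informative SNPs: adjusted = raw x (grand mean SNPs /
#' mean SNPs among that level's transcripts), compensating for better
#' powered (many-SNP) transcripts being overrepresented at high levels.
#'
#' @param fold Per-transcript fold difference.
#' @param n_snps Per-transcript informative-SNP count.
#' @param has_variant Logical (or named list of logicals, one per class)
#'   per transcript: carries at least one vicinity variant.
#' @param levels Lower fold bounds (default `c(1.5, 2, 2.5, 3, 3.5)`).
#' @param upper Upper fold bound (default 9).
#' @return data.frame with `class`, `level`, `n`, `raw`, `adjusted`.
#' @export
adjusted_ai_proportions <- function(fold, n_snps, has_variant,
                                    levels = c(1.5, 2, 2.5, 3, 3.5),
                                    upper = 9) {
  if (!is.list(has_variant)) has_variant <- list(all = has_variant)
  grand <- mean(n_snps[!is.na(fold) & fold <= upper])
  out <- list()
  for (cl in names(has_variant)) {
    hv <- has_variant[[cl]]
    for (lv in levels) {
      sel <- !is.na(fold) & fold >= lv & fold <= upper
      if (!any(sel)) {
        warning("no transcripts at level ", lv)
        next
      }
      raw <- mean(hv[sel])
      adj <- raw * grand / mean(n_snps[sel])
      out[[length(out) + 1]] <- data.frame(class = cl, level = lv,
                                           n = sum(sel), raw = raw,
                                           adjusted = adj)
    }
  }
  do.call(rbind, out)
}

#' Correlate promoter accessibility with nearby DHS bins
#'
#' The promoter signal of a transcript is the mean normalized bin score
#' over the bins overlapping TSS +/- `promoter_halfwidth`, per dataset.
#' Each DHS bin within `max_dist` of the TSS is then correlated (Pearson,
#' across datasets) with that promoter vector. Zero-variance vectors are
#' skipped.
#'
#' @param signal Matrix datasets x bins of normalized signal.
#' @param grid The [bin_grid()] the columns refer to.
#' @param transcripts data.frame with `transcript`, `chrom`, `tss`
#'   (1-based), `strand`.
#' @param promoter_halfwidth Promoter half-width in bp (default 500).
#' @param max_dist Maximum TSS distance in bp (default 1 Mb).
#' @param candidate_bins Optional bin ids to restrict correlation targets
#'   (e.g. panel DHS bins); default all bins in range.
#' @return data.frame of links: `transcript`, `bin_id`, `r`, `distance`
#'   (bin start minus TSS, bp).
#' @export
correlate_promoter_dhs <- function(signal, grid, transcripts,
                                   promoter_halfwidth = 500,
                                   max_dist = 1e6, candidate_bins = NULL) {
  if (nrow(signal) < 3) stop("need at least 3 datasets for correlation")
  links <- list()
  for (i in seq_len(nrow(transcripts))) {
    tss0 <- transcripts$tss[i] - 1L
    chrom <- transcripts$chrom[i]
    pb <- pos_to_bin(grid, rep(chrom, 2),
                     c(max(0, tss0 - promoter_halfwidth),
                       min(grid$chrom_sizes[[chrom]] - 1,
                           tss0 + promoter_halfwidth)))
    prom_bins <- pb[1]:pb[2]
    pvec <- rowMeans(signal[, prom_bins, drop = FALSE])
    if (stats::sd(pvec) == 0) next
    lo <- pos_to_bin(grid, chrom, max(0, tss0 - max_dist))
    hi <- pos_to_bin(grid, chrom, min(grid$chrom_sizes[[chrom]] - 1,
                                      tss0 + max_dist))
    cand <- setdiff(lo:hi, prom_bins)
    if (!is.null(candidate_bins)) cand <- intersect(cand, candidate_bins)
    if (!length(cand)) next
    sub <- signal[, cand, drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    ok <- sds > 0
    if (!any(ok)) next
    r <- as.numeric(stats::cor(pvec, sub[, ok, drop = FALSE]))
    starts <- bin_to_interval(grid, cand[ok])$start
    links[[length(links) + 1]] <- data.frame(
      transcript = transcripts$transcript[i],
      bin_id = cand[ok], r = r, distance = starts - tss0,
      stringsAsFactors = FALSE)
  }
  if (!length(links))
    return(data.frame(transcript = character(0), bin_id = integer(0),
                      r = numeric(0), distance = numeric(0)))
  do.call(rbind, links)
}

#' Fold enrichment of a variant predicate in AI transcripts
#'
#' Fold = P(at least one qualifying variant | AI transcript) /
#' P(at least one qualifying variant | all tested transcripts).
#'
#' @param ai_transcripts,all_transcripts Character vectors of transcript
#'   ids (the AI set is typically a subset of the tested set).
#' @param has_variant Named logical: per transcript, does the predicate
#'   hold (names are transcript ids).
#' @return Fold enrichment (`NA` when the background proportion is zero).
#' @export
ai_enrichment <- function(ai_transcripts, all_transcripts, has_variant) {
  if (!length(ai_transcripts) || !length(all_transcripts))
    stop("both transcript sets must be non-empty")
  p_ai <- mean(has_variant[ai_transcripts])
  p_all <- mean(has_variant[all_transcripts])
  if (is.na(p_all) || p_all == 0) return(NA_real_)
  p_ai / p_all
}

#' AI enrichment trend across promoter-correlation thresholds
#'
#' Computes [ai_enrichment()] for the predicate "carries a rare or novel
#' variant in a DHS linked to the promoter at Pearson r above the
#' threshold", for each threshold, and fits an OLS line of fold on
#' threshold. Because the linked-DHS sets are nested across thresholds
#' the per-threshold folds are correlated; the slope p-value is reported
#' as a descriptive trend summary, not a calibrated test (see the
#' dose-response trend test for a calibrated alternative).
#'
#' @param ai_transcripts,all_transcripts Transcript id vectors.
#' @param links Link table from [correlate_promoter_dhs()].
#' @param variant_bins Bin ids containing qualifying (e.g. rare or novel)
#'   variants.
#' @param thresholds Correlation thresholds (default 0.5..0.9).
#' @return List with `table` (threshold, fold) and `slope`, `p_value`.
#' @export
ai_enrichment_trend <- function(ai_transcripts, all_transcripts, links,
                                variant_bins,
                                thresholds = seq(0.5, 0.9, by = 0.1)) {
  folds <- vapply(thresholds, function(th) {
    linked <- links[links$r > th & links$bin_id %in% variant_bins, ]
    has <- stats::setNames(all_transcripts %in% linked$transcript,
                           all_transcripts)
    ai_enrichment(ai_transcripts, all_transcripts, has)
  }, numeric(1))
  tab <- data.frame(threshold = thresholds, fold = folds)
  ok <- !is.na(folds)
  if (sum(ok) >= 3) {
    fit <- suppressWarnings(
      summary(stats::lm(fold ~ threshold, data = tab[ok, ])))$coefficients
    list(table = tab, slope = fit["threshold", 1],
         p_value = fit["threshold", 4])
  } else list(table = tab, slope = NA_real_, p_value = NA_real_)
}

#' Restrict ASE records to individuals homozygous at the top eSNP
#'
#' Keeps (transcript, individual) records where the individual is
#' homozygous (0/0 or 1/1) for the transcript's top established common
#' eSNP, removing the common-variant contribution to allelic imbalance.
#' Transcripts without an eSNP annotation are excluded from the
#' homozygous subset (they remain in the unrestricted analysis).
#'
#' @param records data.frame with `transcript`, `individual`.
#' @param esnp_genotypes data.frame with `transcript`, `individual`,
#'   `gt` (`"0/0"`, `"0/1"`, `"1/1"`).
#' @return The homozygous subset of `records`.
#' @export
stratify_homozygous <- function(records, esnp_genotypes) {
  key <- paste(records$transcript, records$individual)
  gkey <- paste(esnp_genotypes$transcript, esnp_genotypes$individual)
  gt <- esnp_genotypes$gt[match(key, gkey)]
  out <- records[!is.na(gt) & gt %in% c("0/0", "1/1"), , drop = FALSE]
  if (!nrow(out)) warning("no homozygous records")
  out
}

#' AI proportion by vicinity variant count (dose response)
#'
#' Stratifies records by the number of qualifying vicinity variants and
#' reports the (SNP-count-adjusted) proportion of AI records per
#' stratum, with a Cochran-Armitage style trend test of AI status on the
#' count.
#'
#' @param ai Logical per record: allelic imbalance (fold in the AI band).
#' @param count Integer per record: qualifying vicinity variants.
#' @param n_snps Optional informative-SNP counts for adjustment.
#' @param max_count Counts at or above this value are pooled (default 3).
#' @return List with `table` (count stratum, n, raw, adjusted) and
#'   `trend_p`.
#' @export
count_dose_response <- function(ai, count, n_snps = NULL, max_count = 3) {
  stratum <- pmin(count, max_count)
  lv <- sort(unique(stratum))
  tab <- do.call(rbind, lapply(lv, function(k) {
    sel <- stratum == k
    raw <- mean(ai[sel])
    adj <- if (is.null(n_snps)) raw
           else raw * mean(n_snps) / mean(n_snps[sel])
    data.frame(count = k, n = sum(sel), raw = raw, adjusted = adj)
  }))
  trend_p <- if (nrow(tab) >= 2) {
    ev <- vapply(lv, function(k) sum(ai[stratum == k]), numeric(1))
    n <- vapply(lv, function(k) sum(stratum == k), numeric(1))
    suppressWarnings(stats::prop.trend.test(ev, n, score = lv)$p.value)
  } else NA_real_
  list(table = tab, trend_p = trend_p)
}

#' Signed variant distances from transcript TSSs
#'
#' @param transcripts data.frame with `chrom`, `tss` (1-based), `strand`.
#' @param variants data.frame with `chrom`, `pos` (1-based).
#' @param max_dist Maximum absolute distance retained.
#' @return Numeric vector of strand-aware signed distances, one per
#'   (transcript, variant) pair within range.
#' @export
variant_tss_distances <- function(transcripts, variants, max_dist = 1e6) {
  out <- lapply(seq_len(nrow(transcripts)), function(i) {
    sel <- variants$chrom == transcripts$chrom[i]
    d <- (variants$pos[sel] - transcripts$tss[i]) *
      ifelse(transcripts$strand[i] == "-", -1, 1)
    d[abs(d) <= max_dist]
  })
  unlist(out)
}

#' Variant enrichment profile by distance from the TSS
#'
#' Sliding-window fold enrichment: at each offset, the per-transcript
#' density of qualifying variants within the window around AI-transcript
#' TSSs divided by the same density around all tested transcripts.
#'
#' @param ai_transcripts,all_transcripts Transcript tables (`chrom`,
#'   `tss`, `strand`) for the AI set and the full tested set.
#' @param variants data.frame with `chrom`, `pos`.
#' @param window Window width in bp (default 80,000).
#' @param step Offset step in bp (default 10,000).
#' @param max_dist Profile half-range in bp (default 500,000).
#' @return data.frame with `offset`, `fold` (windows with zero background
#'   density omitted).
#' @export
tss_distance_enrichment <- function(ai_transcripts, all_transcripts,
                                    variants, window = 80000, step = 10000,
                                    max_dist = 5e5) {
  d_ai <- variant_tss_distances(ai_transcripts, variants,
                                max_dist + window / 2)
  d_all <- variant_tss_distances(all_transcripts, variants,
                                 max_dist + window / 2)
  offsets <- seq(-max_dist, max_dist, by = step)
  rows <- lapply(offsets, function(o) {
    lo <- o - window / 2; hi <- o + window / 2
    dens_ai <- sum(d_ai >= lo & d_ai < hi) / nrow(ai_transcripts)
    dens_all <- sum(d_all >= lo & d_all < hi) / nrow(all_transcripts)
    if (dens_all == 0) return(NULL)
    data.frame(offset = o, fold = dens_ai / dens_all)
  })
  do.call(rbind, rows)
}

#' Residual allelic-imbalance variance explained by rare variants
#'
#' Coefficient of determination from the ordinary least squares fit of
#' log2 fold difference on the number of rare-plus-novel vicinity
#' variants, over eSNP-homozygous records (where common-variant effects
#' have been removed by stratification).
#'
#' @param fold Per-record fold difference (>= 1).
#' @param count Per-record rare-plus-novel vicinity variant count.
#' @return R-squared in `[0, 1]` (`NA` when the response has zero
#'   variance).
#' @export
residual_variance_explained <- function(fold, count) {
  ok <- !is.na(fold) & !is.na(count)
  if (sum(ok) < 10) stop("need at least 10 records")
  y <- log2(fold[ok])
  if (stats::sd(y) == 0) return(NA_real_)
  suppressWarnings(summary(stats::lm(y ~ count[ok])))$r.squared
}
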