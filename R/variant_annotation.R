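#' Quality-filter genotype calls and variant sites
#'
#' Applies the sequencing-QC rule per genotype call: read depth,
#' genotyping quality and site mapping quality must meet their thresholds,
#' and heterozygous calls must additionally have a reference-read fraction
#' inside `ab_range` (the allele-balance rule applies to heterozygotes
#' only; homozygous calls would rarely satisfy it). Indel records are
#' excluded entirely; a call with a missing required field fails QC and is
#' logged. A site survives when at least one of its calls passes.
#'
#' @param variants data.frame with `variant_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `mq`.
#' @param genotypes Long data.frame with `variant_id`, `sample`, `gt`
#'   (`"0/0"`, `"0/1"`, `"1/1"`), `dp`, `gq`, `ad_ref` (reference-allele
#'   read count).
#' @param dp_min,gq_min,mq_min,ab_range QC thresholds (defaults 10, 70,
#'   50, and 0.10-0.90 inclusive).
#' @return List with `variants` (passing sites), `genotypes` (passing
#'   calls) and `rejections` (call-level log with reasons).
#' @export
qc_filter <- function(variants, genotypes, dp_min = 10, gq_min = 70,
                      mq_min = 50, ab_range = c(0.10, 0.90)) {
  is_snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref != variants$alt
  snv_ids <- variants$variant_id[is_snv]
  g <- genotypes[genotypes$variant_id %in% snv_ids, , drop = FALSE]
  mq <- variants$mq[match(g$variant_id, variants$variant_id)]
  het <- g$gt %in% c("0/1", "1/0")
  ab <- ifelse(is.na(g$dp) | g$dp == 0, NA, g$ad_ref / g$dp)

  reason <- character(nrow(g))
  fail <- function(cond, why) {
    miss <- is.na(cond)
    hit <- !miss & cond
    reason[hit & reason == ""] <<- why
    reason[miss & reason == ""] <<- paste0(why, " (missing)")
  }
  fail(g$dp < dp_min, "low_depth")
  fail(g$gq < gq_min, "low_gq")
  fail(mq < mq_min, "low_mq")
  ab_bad <- het & (ab < ab_range[1] | ab > ab_range[2])
  ab_bad[het & is.na(ab)] <- NA
  ab_bad[!het] <- FALSE
  fail(ab_bad, "allele_balance")

  pass <- reason == ""
  kept_sites <- intersect(snv_ids, unique(g$variant_id[pass]))
  dropped_indels <- variants$variant_id[!is_snv]
  rejections <- rbind(
    data.frame(variant_id = g$variant_id[!pass], sample = g$sample[!pass],
               reason = reason[!pass], stringsAsFactors = FALSE),
    if (length(dropped_indels))
      data.frame(variant_id = dropped_indels, sample = NA_character_,
                 reason = "indel", stringsAsFactors = FALSE))
  list(variants = variants[variants$variant_id %in% kept_sites, , drop = FALSE],
       genotypes = g[pass, , drop = FALSE],
       rejections = rejections)
}

#' Classify variant frequency as common, rare or novel
#'
#' Common: minor allele frequency >= 1% in the frequency reference.
#' Rare: present in the reference (or the known-sites list) with MAF < 1%.
#' Novel: absent from both catalogues. Matching requires identical
#' chrom, pos, ref and alt; a position match with a different alternate
#' allele counts as novel at the allele level.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param freq_ref data.frame with `chrom`, `pos`, `ref`, `alt`, `af`
#'   (alternate-allele frequency; folded to MAF before thresholding).
#' @param known_sites Optional data.frame of additional catalogued sites
#'   (`chrom`, `pos`, `ref`, `alt`) without frequencies.
#' @param maf_common MAF threshold for common (default 0.01).
#' @return Factor with levels `common`, `rare`, `novel`.
#' @export
classify_frequency <- function(variants, freq_ref, known_sites = NULL,
                               maf_common = 0.01) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  i <- match(key(variants), key(freq_ref))
  af <- freq_ref$af[i]
  maf <- pmin(af, 1 - af)
  known_extra <- if (!is.null(known_sites) && nrow(known_sites))
    key(variants) %in% key(known_sites) else rep(FALSE, nrow(variants))
  cls <- ifelse(!is.na(maf) & maf >= maf_common, "common",
         ifelse((!is.na(maf)) | known_extra, "rare", "novel"))
  factor(cls, levels = c("common", "rare", "novel"))
}

cds_model <- function(transcripts) {
  split(transcripts, transcripts$tx_id)
}

#' Annotate the coding effect of SNVs against simple gene models
#'
#' For a variant inside a transcript's CDS the containing codon is
#' translated for the reference and the alternate allele (strand-aware)
#' and the effect assigned by amino-acid comparison: synonymous,
#' non-synonymous, or stop-gained (sense codon turned into a stop).
#' Variants outside every CDS are non-coding. A CDS variant whose stated
#' reference base disagrees with the genome is rejected for that record
#' and logged (`NA` effect).
#'
#' @param variants data.frame with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param transcripts CDS exon table: data.frame with `tx_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end` (0-based half-open); per
#'   transcript the summed exon length must be divisible by 3.
#' @param genome Named `DNAStringSet` (or character vector) of chromosome
#'   sequences.
#' @return Factor with levels `synonymous`, `non-synonymous`,
#'   `stop-gained`, `non-coding`; `NA` for rejected records (attribute
#'   `"rejected"` lists their indices).
#' @export
annotate_coding_effect <- function(variants, transcripts, genome) {
  genome <- as_genome_strings(genome)
  txs <- cds_model(transcripts)
  for (tx in txs) {
    if (sum(tx$end - tx$start) %% 3 != 0)
      stop("CDS length of ", tx$tx_id[1], " not divisible by 3")
  }
  out <- rep(NA_character_, nrow(variants))
  rejected <- integer(0)
  for (v in seq_len(nrow(variants))) {
    pos0 <- variants$pos[v] - 1L
    eff <- "non-coding"
    for (tx in txs) {
      if (tx$chrom[1] != variants$chrom[v]) next
      hit <- which(pos0 >= tx$start & pos0 < tx$end)
      if (!length(hit)) next
      # genomic coordinates of the CDS in transcription order
      coords <- unlist(lapply(seq_len(nrow(tx)),
                              function(i) tx$start[i]:(tx$end[i] - 1L)))
      coords <- sort(coords)
      minus <- tx$strand[1] == "-"
      if (minus) coords <- rev(coords)
      cds_pos <- match(pos0, coords)
      codon_i <- (cds_pos - 1L) %/% 3L
      codon_coords <- coords[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
      bases <- substring(genome[[variants$chrom[v]]],
                         codon_coords + 1L, codon_coords + 1L)
      if (minus) bases <- chartr("ACGT", "TGCA", bases)
      ref_base <- variants$ref[v]; alt_base <- variants$alt[v]
      genome_base <- substring(genome[[variants$chrom[v]]], pos0 + 1L, pos0 + 1L)
      if (genome_base != ref_base) {
        rejected <- c(rejected, v)
        eff <- NA_character_
        break
      }
      within <- which(codon_coords == pos0)
      ref_codon <- paste(bases, collapse = "")
      alt_bases <- bases
      alt_bases[within] <- if (minus) chartr("ACGT", "TGCA", alt_base) else alt_base
      alt_codon <- paste(alt_bases, collapse = "")
      aa_ref <- as.character(Biostrings::translate(Biostrings::DNAString(ref_codon)))
      aa_alt <- as.character(Biostrings::translate(Biostrings::DNAString(alt_codon)))
      eff <- if (aa_ref == aa_alt) "synonymous"
             else if (aa_alt == "*" && aa_ref != "*") "stop-gained"
             else "non-synonymous"
      break
    }
    out[v] <- eff
  }
  res <- factor(out, levels = c("synonymous", "non-synonymous",
                                "stop-gained", "non-coding"))
  attr(res, "rejected") <- rejected
  res
}

as_genome_strings <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    stats::setNames(as.list(as.character(genome)), names(genome))
  } else as.list(genome)
}

#' DHS cell-type sharing level at variant positions
#'
#' @param variants data.frame with `chrom`, `pos` (1-based).
#' @param panel A `capture_panel` with sharing annotations.
#' @return Integer vector: 0 for positions outside the panel's DHS bins,
#'   otherwise the containing bin's sharing level (1..K).
#' @export
assign_dhs_sharing <- function(variants, panel) {
  bin <- pos_to_bin(panel$grid, variants$chrom, variants$pos - 1L)
  sh <- panel$bins$sharing[match(bin, panel$bins$bin_id)]
  ifelse(is.na(sh), 0L, sh)
}

#' Enrichment of rare/novel vs common variants across sharing levels
#'
#' For each sharing level k (variants in DHS bins carried by k cell
#' types), the fold enrichment is the rare-or-novel to common ratio at
#' level k divided by the same ratio over all DHS variants. An unweighted
#' ordinary least squares regression of fold on level gives the trend
#' slope with a two-sided t-test p-value. Levels without common variants
#' are omitted with a warning.
#'
#' @param class Factor (`common`/`rare`/`novel`) per variant.
#' @param level Integer sharing level per variant; level 0 (outside DHS)
#'   is ignored.
#' @param class_sets Named list mapping a contrast label to the classes
#'   counted in its numerator.
#' @return List with `table` (level, class_set, numerator/denominator
#'   counts, fold) and `fits` (class_set, slope, p_value).
#' @export
sharing_level_enrichment <- function(class, level,
    class_sets = list(rare = "rare", novel = "novel",
                      rare_novel = c("rare", "novel"))) {
  keep <- level >= 1
  class <- class[keep]; level <- level[keep]
  levels_used <- sort(unique(level))
  if (length(levels_used) < 2) stop("need at least two populated sharing levels")
  tabs <- list(); fits <- list()
  for (nm in names(class_sets)) {
    num_all <- sum(class %in% class_sets[[nm]])
    den_all <- sum(class == "common")
    if (den_all == 0) stop("no common variants in DHS")
    rows <- lapply(levels_used, function(k) {
      data.frame(class_set = nm, level = k,
                 n_numerator = sum(class %in% class_sets[[nm]] & level == k),
                 n_common = sum(class == "common" & level == k))
    })
    tab <- do.call(rbind, rows)
    drop <- tab$n_common == 0
    if (any(drop))
      warning(sum(drop), " level(s) without common variants omitted")
    tab <- tab[!drop, , drop = FALSE]
    if (num_all == 0) {
      warning("no ", nm, " variants in DHS; fold undefined")
      tab$fold <- NA_real_
      fits[[nm]] <- data.frame(class_set = nm, slope = NA_real_,
                               p_value = NA_real_)
    } else {
      tab$fold <- (tab$n_numerator / tab$n_common) / (num_all / den_all)
      fit <- stats::lm(fold ~ level, data = tab)
      # a noise-free fold profile fits exactly; that is fine here
      cf <- suppressWarnings(summary(fit))$coefficients
      fits[[nm]] <- data.frame(class_set = nm, slope = cf["level", 1],
                               p_value = cf["level", 4])
    }
    tabs[[nm]] <- tab
  }
  list(table = do.call(rbind, tabs), fits = do.call(rbind, fits))
}

#' Proportion of selectively constrained variants per frequency class
#'
#' For each class and each score threshold, the proportion of variants at
#' or above the threshold; variants with a missing score stay in the
#' denominator and count as below threshold (configurable). Pairwise
#' class contrasts are tested with [fisher_enrichment()].
#'
#' @param class Frequency class factor per variant.
#' @param score Numeric conservation/deleteriousness score per variant
#'   (e.g. GERP++ or CADD); may contain `NA`.
#' @param thresholds Score thresholds (default GERP-style `c(1, 2)`).
#' @param drop_missing If `TRUE`, variants with missing scores are
#'   removed from denominators instead.
#' @return List with `proportions` and `contrasts` data.frames.
#' @export
constraint_proportions <- function(class, score, thresholds = c(1, 2),
                                   drop_missing = FALSE) {
  stopifnot(length(class) == length(score))
  if (drop_missing) {
    keep <- !is.na(score)
    class <- class[keep]; score <- score[keep]
  }
  hit <- !is.na(score) & outer(score, thresholds, `>=`)
  cls <- levels(factor(class))
  props <- do.call(rbind, lapply(seq_along(thresholds), function(ti) {
    do.call(rbind, lapply(cls, function(cl) {
      n <- sum(class == cl)
      data.frame(class = cl, threshold = thresholds[ti],
                 n = n,
                 prop = if (n == 0) NA_real_ else sum(hit[class == cl, ti]) / n)
    }))
  }))
  pairs <- if (length(cls) >= 2) utils::combn(cls, 2) else NULL
  contrasts <- NULL
  if (!is.null(pairs)) {
    contrasts <- do.call(rbind, lapply(seq_along(thresholds), function(ti) {
      do.call(rbind, apply(pairs, 2, function(p) {
        a_in <- sum(hit[class == p[1], ti]); a_n <- sum(class == p[1])
        b_in <- sum(hit[class == p[2], ti]); b_n <- sum(class == p[2])
        if (a_n == 0 || b_n == 0) return(NULL)
        fe <- fisher_enrichment(a_in, a_n - a_in, b_in, b_n - b_in)
        data.frame(class_a = p[1], class_b = p[2],
                   threshold = thresholds[ti],
                   odds_ratio = fe$odds_ratio, p_value = fe$p_value)
      }))
    }))
  }
  list(proportions = props, contrasts = contrasts)
}

#' Class-by-annotation variant accounting table
#'
#' Summary in the shape used for reporting capture-wide variant yields:
#' rows all / coding / non-synonymous / synonymous / stop-gained /
#' non-coding / all-DHS, columns all / common / rare / novel. By
#' construction total = coding + non-coding per class.
#'
#' @param class Frequency class factor.
#' @param effect Coding-effect factor from [annotate_coding_effect()].
#' @param sharing Sharing level from [assign_dhs_sharing()].
#' @return data.frame of counts.
#' @export
variant_summary_table <- function(class, effect, sharing) {
  coding <- effect %in% c("synonymous", "non-synonymous", "stop-gained")
  rows <- list(
    all = rep(TRUE, length(class)),
    coding = coding,
    `non-synonymous` = effect == "non-synonymous",
    synonymous = effect == "synonymous",
    `stop-gained` = effect == "stop-gained",
    `non-coding` = !coding,
    `all-DHS` = sharing >= 1)
  cols <- list(all = rep(TRUE, length(class)),
               common = class == "common", rare = class == "rare",
               novel = class == "novel")
  out <- sapply(cols, function(cl) sapply(rows, function(rw) sum(rw & cl)))
  data.frame(category = names(rows), out, row.names = NULL,
             check.names = FALSE)
}
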