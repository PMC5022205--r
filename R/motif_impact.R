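DNA <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' Stores per-position base probabilities with a FIMO-style pseudocount
#' (total mass 0.01 distributed according to the background) and the
#' derived log2 odds scoring matrix against a 0-order background.
#'
#' @param id Motif identifier.
#' @param probs 4 x w numeric matrix (rows A, C, G, T), each column
#'   summing to 1 within 1e-9.
#' @param background Background base distribution (default uniform 0.25).
#' @param pseudocount Total pseudocount mass (default 0.01).
#' @return A `pwm` object (list with `id`, `probs`, `background`,
#'   `scores`, `width`).
#' @export
new_pwm <- function(id, probs, background = rep(0.25, 4),
                    pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop("probs must have 4 rows (A, C, G, T)")
  w <- ncol(probs)
  if (w < 1 || w > 31) stop("PWM width must be in 1..31")
  if (any(abs(colSums(probs) - 1) > 1e-4))
    stop("each PWM column must sum to 1")
  probs <- sweep(probs, 2, colSums(probs), `/`)
  dimnames(probs) <- list(DNA, NULL)
  background <- background / sum(background)
  adj <- sweep(probs, 1, pseudocount * background, `+`) / (1 + pseudocount)
  if (any(abs(colSums(adj) - 1) > 1e-9)) stop("pseudocount normalization failed")
  dimnames(adj) <- list(DNA, NULL)
  scores <- log2(adj / background)
  structure(list(id = id, probs_raw = probs, probs = adj,
                 background = background, scores = scores, width = w),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$id, "width", x$width, "consensus",
      paste(DNA[apply(x$probs, 2, which.max)], collapse = ""), "\n")
  invisible(x)
}

#' Discretized null score distribution of a PWM
#'
#' Dynamic programming over a discretized log-odds score axis: position
#' scores are rounded to a common unit (`(max - min) / n_bins` of the
#' attainable score range) and the distribution of the total score of a
#' random w-mer under the background model is built column by column.
#' The returned tail function gives, for any score, the probability that
#' a random w-mer scores at least as high.
#'
#' @param pwm A [new_pwm()] object.
#' @param n_bins Number of discretization bins (default 500,000). The
#'   resolution must be fine enough that distinct w-mer scores never
#'   fall within the accumulated rounding slack of one another;
#'   otherwise a misclassified w-mer shifts the p-value by its whole
#'   background mass, which at small widths exceeds any useful
#'   tolerance.
#' @return List with `unit`, `origin` (score of integer bin 0), and
#'   `tail` (tail probabilities indexed by integer bin + 1).
#' @export
pwm_score_dist <- function(pwm, n_bins = 5e5) {
  s <- pwm$scores
  col_min <- apply(s, 2, min)
  col_max <- apply(s, 2, max)
  range <- sum(col_max) - sum(col_min)
  unit <- if (range > 0) range / n_bins else 1
  iscore <- round(sweep(s, 2, col_min) / unit)
  max_int <- sum(apply(iscore, 2, max))
  pdf <- 1
  for (j in seq_len(pwm$width)) {
    shifts <- iscore[, j]
    new <- numeric(length(pdf) + max(shifts))
    for (b in 1:4) {
      k <- shifts[b]
      idx <- (k + 1):(k + length(pdf))
      new[idx] <- new[idx] + pdf * pwm$background[b]
    }
    pdf <- new
  }
  length(pdf) <- max_int + 1
  pdf[is.na(pdf)] <- 0
  tail <- rev(cumsum(rev(pdf)))
  list(unit = unit, origin = sum(col_min), tail = tail)
}

#' P-value of a log-odds score under the background model
#'
#' Probability that a random w-mer drawn from the background scores at
#' least as high as `score`, looked up in the discretized DP
#' distribution. The query bin is lowered by the worst-case accumulated
#' per-position rounding slack, so a w-mer attaining exactly `score` is
#' always counted in its own tail (the estimate errs, if at all, on the
#' conservative side by the mass lying within the slack window).
#'
#' @param pwm A [new_pwm()] object.
#' @param score Observed log2 odds score.
#' @param dist Optional precomputed [pwm_score_dist()] (recomputed
#'   otherwise).
#' @return p-value in `(0, 1]`.
#' @export
pvalue_from_score <- function(pwm, score, dist = NULL) {
  if (is.null(dist)) dist <- pwm_score_dist(pwm)
  slack <- pwm$width %/% 2 + 1
  k <- round((score - dist$origin) / dist$unit) - slack
  k <- pmin(pmax(k, 0), length(dist$tail) - 1)
  dist$tail[k + 1]
}

#' Reference and alternate sequence windows around a variant
#'
#' Extracts the genomic sequence centered on the variant position with
#' `flank` bases on each side (31 nt windows at the default). The
#' alternate window differs from the reference window only at the
#' variant base. Windows are truncated (and flagged) near chromosome
#' ends; a mismatch between the VCF reference allele and the genome is
#' an error.
#'
#' @param variant One-row data.frame with `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param genome Named `DNAStringSet` or character vector.
#' @param flank Flank size in nt (default 15).
#' @return List with `ref`, `alt` (character), `center` (0-based index of
#'   the variant within the window) and `truncated`.
#' @export
extract_allele_windows <- function(variant, genome, flank = 15) {
  genome <- as_genome_strings(genome)
  chrom_seq <- genome[[variant$chrom]]
  if (is.null(chrom_seq)) stop("unknown chromosome ", variant$chrom)
  L <- nchar(chrom_seq)
  pos <- variant$pos
  lo <- max(1, pos - flank); hi <- min(L, pos + flank)
  win <- substring(chrom_seq, lo, hi)
  center <- pos - lo
  if (substring(win, center + 1, center + 1) != variant$ref)
    stop("genome base does not match reference allele at ",
         variant$chrom, ":", pos)
  alt <- win
  substring(alt, center + 1, center + 1) <- variant$alt
  list(ref = win, alt = alt, center = center,
       truncated = (pos - flank < 1) || (pos + flank > L))
}

revcomp <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

score_wmer <- function(pwm, wmer) {
  b <- match(strsplit(wmer, "")[[1]], DNA)
  sum(pwm$scores[cbind(b, seq_len(pwm$width))])
}

#' Scan one allele window with a PWM
#'
#' Evaluates every placement, on both strands, whose footprint covers the
#' variant position, and returns the best-scoring one with its DP
#' p-value. Placements not covering the variant are excluded even if they
#' score higher (only motifs directly overlapping the variant count).
#'
#' @param seq Window sequence (character).
#' @param center 0-based index of the variant within `seq`.
#' @param pwm A [new_pwm()] object.
#' @param alpha Per-match significance threshold.
#' @param dist Optional precomputed [pwm_score_dist()].
#' @return A motif call: list with `score`, `p_value`, `offset` (0-based
#'   placement start in the window), `strand`, `significant`; `NULL`
#'   score (verdict impossible) when the motif does not fit the window.
#' @export
scan_allele <- function(seq, center, pwm, alpha, dist = NULL) {
  L <- nchar(seq)
  w <- pwm$width
  if (w > L)
    return(list(score = NA_real_, p_value = NA_real_, offset = NA_integer_,
                strand = NA_character_, significant = FALSE))
  if (is.null(dist)) dist <- pwm_score_dist(pwm)
  starts <- max(0, center - w + 1):min(L - w, center)
  best <- NULL
  rc <- revcomp(seq)
  for (st in starts) {
    fw <- substring(seq, st + 1, st + w)
    sc_f <- score_wmer(pwm, fw)
    # the minus-strand placement occupying the same genomic footprint
    rv <- substring(rc, L - st - w + 1, L - st)
    sc_r <- score_wmer(pwm, rv)
    for (cand in list(list(sc = sc_f, strand = "+"),
                      list(sc = sc_r, strand = "-"))) {
      if (is.null(best) || cand$sc > best$score)
        best <- list(score = cand$sc, offset = st, strand = cand$strand)
    }
  }
  p <- pvalue_from_score(pwm, best$score, dist)
  list(score = best$score, p_value = p, offset = best$offset,
       strand = best$strand, significant = p < alpha)
}

#' Bonferroni-corrected significance threshold
#'
#' @param family_alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests (the study corrects over the number of
#'   variants scanned).
#' @return `family_alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 351088)  # ~1.42e-7
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  family_alpha / n_tests
}

#' Classify motif creation and disruption per variant
#'
#' For every variant and every PWM, both allele windows are scanned at
#' placements overlapping the variant. A motif is created when only the
#' alternate allele reaches significance, disrupted when only the
#' reference allele does; significance for both alleles (or neither)
#' yields verdict `none` (the score change is still reported).
#'
#' @param variants data.frame with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param genome Named `DNAStringSet` or character vector.
#' @param pwms List of [new_pwm()] objects.
#' @param alpha Per-match significance threshold (e.g.
#'   [bonferroni_alpha()] over the number of variants).
#' @param flank Window flank (default 15).
#' @return List with `calls` (one row per variant x PWM: scores, p-values,
#'   verdict) and `flags` (per variant: `any_created`, `any_disrupted`).
#' @export
classify_motif_impact <- function(variants, genome, pwms, alpha, flank = 15) {
  genome <- as_genome_strings(genome)
  dists <- lapply(pwms, pwm_score_dist)
  ids <- vapply(pwms, function(p) p$id, character(1))
  rows <- vector("list", nrow(variants) * length(pwms))
  r <- 0
  for (v in seq_len(nrow(variants))) {
    win <- extract_allele_windows(variants[v, , drop = FALSE], genome, flank)
    for (m in seq_along(pwms)) {
      ref_call <- scan_allele(win$ref, win$center, pwms[[m]], alpha, dists[[m]])
      alt_call <- scan_allele(win$alt, win$center, pwms[[m]], alpha, dists[[m]])
      verdict <- if (isTRUE(alt_call$significant) && !isTRUE(ref_call$significant))
        "created"
      else if (isTRUE(ref_call$significant) && !isTRUE(alt_call$significant))
        "disrupted"
      else "none"
      r <- r + 1
      rows[[r]] <- data.frame(
        variant_id = variants$variant_id[v], pwm = ids[m],
        ref_score = ref_call$score, ref_p = ref_call$p_value,
        alt_score = alt_call$score, alt_p = alt_call$p_value,
        score_delta = alt_call$score - ref_call$score,
        verdict = verdict, stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  flags <- do.call(rbind, lapply(split(calls, calls$variant_id), function(d)
    data.frame(variant_id = d$variant_id[1],
               any_created = any(d$verdict == "created"),
               any_disrupted = any(d$verdict == "disrupted"),
               stringsAsFactors = FALSE)))
  flags <- flags[match(unique(variants$variant_id), flags$variant_id), ]
  rownames(flags) <- NULL
  list(calls = calls, flags = flags)
}

#' Motif-impact proportions by frequency class
#'
#' Proportion of variants in each frequency class with at least one
#' created (resp. disrupted) motif, with pairwise Fisher exact contrasts.
#'
#' @param class Frequency class factor per variant.
#' @param flag Logical per variant (e.g. `any_created`).
#' @return List with `proportions` and `contrasts` data.frames.
#' @export
impact_proportion_test <- function(class, flag) {
  stopifnot(length(class) == length(flag))
  cls <- levels(factor(class))
  populated <- cls[vapply(cls, function(cl) sum(class == cl) > 0, logical(1))]
  if (length(populated) < 2) {
    warning("fewer than two populated classes")
  }
  props <- do.call(rbind, lapply(populated, function(cl)
    data.frame(class = cl, n = sum(class == cl),
               prop = mean(flag[class == cl]))))
  contrasts <- NULL
  if (length(populated) >= 2) {
    pairs <- utils::combn(populated, 2)
    contrasts <- do.call(rbind, apply(pairs, 2, function(p) {
      a <- sum(flag & class == p[1]); an <- sum(class == p[1])
      b <- sum(flag & class == p[2]); bn <- sum(class == p[2])
      fe <- fisher_enrichment(a, an - a, b, bn - b)
      data.frame(class_a = p[1], class_b = p[2],
                 odds_ratio = fe$odds_ratio, p_value = fe$p_value)
    }))
  }
  list(proportions = props, contrasts = contrasts)
}
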