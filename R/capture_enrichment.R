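#' Fraction of lead SNPs captured by the panel
#'
#' A lead SNP counts as captured when its own position, or the position of
#' at least one of its LD proxies, falls inside a panel interval. Proxy
#' computation itself (e.g. r-squared > 0.9 tables) is consumed as input.
#'
#' @param hits data.frame with `id`, `chrom`, `pos` (1-based SNP
#'   positions).
#' @param panel A `capture_panel` (or any `GRanges` of target intervals).
#' @param proxies Optional data.frame with `lead_id`, `chrom`, `pos`.
#' @return List with `fraction`, `n_captured`, `n_total` and the captured
#'   id subset.
#' @export
capture_fraction <- function(hits, panel, proxies = NULL) {
  if (!nrow(hits)) stop("empty hit set")
  iv <- if (inherits(panel, "capture_panel")) panel$intervals else panel
  in_panel <- function(chrom, pos) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    IRanges::overlapsAny(gr, iv)
  }
  captured <- hits$id[in_panel(hits$chrom, hits$pos)]
  if (!is.null(proxies) && nrow(proxies)) {
    hit_prox <- proxies[in_panel(proxies$chrom, proxies$pos), , drop = FALSE]
    captured <- union(captured, intersect(hits$id, hit_prox$lead_id))
  }
  list(fraction = length(captured) / nrow(hits),
       n_captured = length(captured), n_total = nrow(hits),
       captured_ids = sort(captured))
}

#' Draw random bin sets as an empirical null
#'
#' Each iteration samples `n_bins` distinct bins uniformly without
#' replacement from the supplied universe (typically the grid minus
#' exclusion masks such as coding regions).
#'
#' @param universe Integer vector of eligible bin ids.
#' @param n_bins Bins per draw.
#' @param iterations Number of draws (study design: 1000).
#' @param seed Integer seed.
#' @return List of integer bin-id vectors, one per iteration.
#' @export
sample_random_bins <- function(universe, n_bins, iterations = 1000, seed = 1) {
  universe <- as.integer(universe)
  if (n_bins > length(universe))
    stop("universe smaller than requested n_bins")
  with_substream(seed, "random_bins",
    lapply(seq_len(iterations), function(i) sample(universe, n_bins)))
}

#' Two-sided Fisher exact test on a 2x2 enrichment table
#'
#' The table is oriented rows = SNP set (hits vs background), columns =
#' in-region vs out-of-region. The p-value is computed by direct
#' enumeration of the conditional hypergeometric distribution, two-sided
#' by summing all tables with probability not exceeding that of the
#' observed one. The odds ratio is the sample odds ratio a*d/(b*c)
#' (infinite when b*c = 0 with a*d > 0).
#'
#' @param hits_in,hits_out,bg_in,bg_out Nonnegative integer cell counts
#'   (a, b, c, d).
#' @return An `enrichment_result`: list with `counts`, `odds_ratio`,
#'   `p_value`, `fold_enrichment`.
#' @export
fisher_enrichment <- function(hits_in, hits_out, bg_in, bg_out) {
  a <- hits_in; b <- hits_out; cc <- bg_in; d <- bg_out
  cells <- c(a, b, cc, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be nonnegative integers")
  if (sum(cells) == 0) stop("all-zero table")
  m <- a + b; n <- cc + d; k <- a + cc
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  p <- sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  fold <- if (cc + d == 0 || cc == 0) {
    if (a == 0) NaN else Inf
  } else (a / (a + b)) / (cc / (cc + d))
  structure(list(counts = c(a = a, b = b, c = cc, d = d),
                 odds_ratio = or, p_value = min(p, 1), fold_enrichment = fold),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("2x2 [%d %d / %d %d]: OR = %.4g, fold = %.4g, p = %.3g\n",
              x$counts[1], x$counts[2], x$counts[3], x$counts[4],
              x$odds_ratio, x$fold_enrichment, x$p_value))
  invisible(x)
}

#' Empirical enrichment against random-region nulls
#'
#' Permutation-style estimator with the add-one rule, so the p-value is
#' never exactly zero: p = (1 + #\{null >= observed\}) / (1 + iterations).
#' Fold enrichment is observed overlap over the mean null overlap.
#'
#' @param observed Observed overlap count.
#' @param null_overlaps Numeric vector of overlap counts from the null
#'   draws (at least 100).
#' @return List with `p_value`, `fold`, and a summary of the null
#'   distribution.
#' @export
empirical_enrichment <- function(observed, null_overlaps) {
  if (length(null_overlaps) < 100)
    stop("need at least 100 null iterations")
  p <- (1 + sum(null_overlaps >= observed)) / (1 + length(null_overlaps))
  mu <- mean(null_overlaps)
  fold <- if (mu == 0) {
    warning("zero mean null overlap; fold reported as Inf")
    Inf
  } else observed / mu
  list(p_value = p, fold = fold,
       null_mean = mu, null_sd = stats::sd(null_overlaps),
       iterations = length(null_overlaps))
}

#' Count lead SNPs overlapping a bin set
#'
#' Helper for the empirical null: how many hit SNPs (directly, or via a
#' proxy when supplied) fall in the given bins.
#'
#' @param hits data.frame `id`, `chrom`, `pos` (1-based).
#' @param bins Integer bin ids.
#' @param grid The [bin_grid()].
#' @param proxies Optional proxy table as in [capture_fraction()].
#' @return Integer count of captured lead SNPs.
#' @export
hits_in_bins <- function(hits, bins, grid, proxies = NULL) {
  bins <- as.integer(bins)
  hit_bin <- pos_to_bin(grid, hits$chrom, hits$pos - 1L)
  captured <- hits$id[!is.na(hit_bin) & hit_bin %in% bins]
  if (!is.null(proxies) && nrow(proxies)) {
    pb <- pos_to_bin(grid, proxies$chrom, proxies$pos - 1L)
    lead_ok <- proxies$lead_id[!is.na(pb) & pb %in% bins]
    captured <- union(captured, intersect(hits$id, lead_ok))
  }
  length(captured)
}
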