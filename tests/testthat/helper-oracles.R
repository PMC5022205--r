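# Independent reference implementations used only to check results.

# Naive panel design: explicit sorts, loops and set operations.
naive_design <- function(counts, cell_type, grid, n_top, block_size = NULL,
                         min_overlap = 0.5, exome = NULL, min_frac = 0.5) {
  ranked <- lapply(seq_len(ncol(counts)), function(s) {
    sig <- counts[, s] / sum(counts[, s])
    df <- data.frame(bin = seq_along(sig), sig = sig)
    df <- df[order(-df$sig, df$bin), ]
    df$bin[seq_len(min(n_top, nrow(df)))]
  })
  sets <- list()
  for (ct in unique(cell_type)) {
    rs <- ranked[cell_type == ct]
    if (!is.null(block_size) && length(rs) > 1) {
      n_strata <- min(lengths(rs)) %/% block_size
      kept <- c()
      for (j in seq_len(n_strata)) {
        idx <- ((j - 1) * block_size + 1):(j * block_size)
        ovs <- c()
        for (x in seq_along(rs)) for (y in seq_along(rs)) if (x < y)
          ovs <- c(ovs, length(intersect(rs[[x]][idx], rs[[y]][idx])) /
                     block_size)
        if (mean(ovs) >= min_overlap) kept <- c(kept, idx)
      }
      rs <- lapply(rs, function(s) s[kept])
    }
    m <- length(rs)
    need <- if (m == 1) 1 else if (m == 2) 2 else ceiling(m / 2)
    all_bins <- sort(unique(unlist(rs)))
    cons <- all_bins[vapply(all_bins, function(b)
      sum(vapply(rs, function(s) b %in% s, logical(1))) >= need, logical(1))]
    if (!is.null(exome)) {
      keep <- vapply(cons, function(b) {
        iv <- bin_to_interval(grid, b)
        covered <- integer(0)
        for (e in seq_len(nrow(exome))) {
          if (exome$chrom[e] != iv$chrom) next
          covered <- union(covered,
                           intersect(seq(iv$start, iv$end - 1),
                                     seq(exome$start[e], exome$end[e] - 1)))
        }
        length(covered) < min_frac * (iv$end - iv$start)
      }, logical(1))
      cons <- cons[keep]
    }
    sets[[ct]] <- cons
  }
  tab <- table(unlist(sets))
  data.frame(bin_id = as.integer(names(tab)), sharing = as.integer(tab))
}

# Two-sided Fisher p by explicit enumeration with binomial coefficients.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  dens <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  obs <- dens[xs == a]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Exact PWM tail probabilities by exhaustive enumeration of all w-mers.
enumerate_pwm_scores <- function(pwm) {
  combos <- expand.grid(rep(list(1:4), pwm$width))
  scores <- as.matrix(combos)
  total <- numeric(nrow(scores))
  prob <- rep(1, nrow(scores))
  for (j in seq_len(pwm$width)) {
    total <- total + pwm$scores[cbind(scores[, j], j)]
    prob <- prob * pwm$background[scores[, j]]
  }
  list(score = total, prob = prob)
}

pwm_pvalue_oracle <- function(enum, score) {
  sum(enum$prob[enum$score >= score - 1e-9])
}
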