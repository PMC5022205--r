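#' Generate a random genome sequence
#'
#' Deterministic given the seed; uniform base composition unless
#' configured otherwise.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param seed Master seed.
#' @param base_probs Probabilities for A, C, G, T.
#' @return Named `DNAStringSet`.
#' @export
make_genome <- function(chrom_sizes, seed = 1,
                        base_probs = c(0.25, 0.25, 0.25, 0.25)) {
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  seqs <- with_substream(seed, "genome", {
    lapply(chrom_sizes, function(L)
      paste(sample(DNA, L, replace = TRUE, prob = base_probs),
            collapse = ""))
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(chrom_sizes)
  out
}

#' Simulate replicated DNase-I hypersensitivity experiments
#'
#' Plants peaks with a known cell-type sharing architecture on a bin
#' grid and draws per-sample read counts: Poisson background everywhere
#' plus Poisson peak signal at planted peaks, independently per
#' replicate. In `noise_free` mode counts are deterministic (zero
#' background, fixed peak height), so the design pipeline must recover
#' the architecture exactly.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param cell_types Character vector of cell-type names (K types).
#' @param replicates Named integer vector: samples per cell type (>= 1).
#' @param peaks_per_level Integer vector over sharing levels 1..K: how
#'   many peaks are carried by exactly that many (randomly chosen) cell
#'   types.
#' @param peak_width_bins Peak width in bins (default 2).
#' @param background_rate Mean background reads per bin (default 1).
#' @param peak_rate Mean additional reads per peak bin (default 50).
#' @param depth Depth multiplier applied to both rates (> 0).
#' @param bin_size Bin width in bp (default 100).
#' @param noise_free Deterministic counts (default FALSE).
#' @param seed Master seed.
#' @return List with `grid`, `counts` (matrix bins x samples),
#'   `sample_info` (sample_id, cell_type, replicate) and `truth`
#'   (`synthetic_truth` with the planted peak table).
#' @export
simulate_dhs_experiments <- function(chrom_sizes, cell_types, replicates,
                                     peaks_per_level,
                                     peak_width_bins = 2,
                                     background_rate = 1, peak_rate = 50,
                                     depth = 1, bin_size = 100,
                                     noise_free = FALSE, seed = 1) {
  if (depth <= 0) stop("depth must be positive")
  if (any(replicates < 1)) stop("need at least one replicate per cell type")
  if (length(peaks_per_level) > length(cell_types))
    stop("more sharing levels than cell types")
  grid <- bin_grid(chrom_sizes, bin_size)
  K <- length(cell_types)
  n_peaks <- sum(peaks_per_level)
  with_substream(seed, "dhs", {
    # non-overlapping peak placements, one grid-wide lattice
    slots <- floor(grid$n_bins / (peak_width_bins + 3))
    if (n_peaks > slots) stop("too many peaks for the grid")
    starts <- if (n_peaks > 0)
      sort(sample(slots, n_peaks)) * (peak_width_bins + 3) - peak_width_bins
    else integer(0)
    peaks <- data.frame(peak_id = character(0), start_bin = integer(0),
                        end_bin = integer(0), level = integer(0),
                        cell_types = character(0))
    if (n_peaks > 0) {
      peaks <- data.frame(peak_id = paste0("peak", seq_len(n_peaks)),
                          start_bin = starts,
                          end_bin = starts + peak_width_bins - 1L,
                          level = rep(seq_along(peaks_per_level),
                                      peaks_per_level))
      peaks$cell_types <- vapply(peaks$level, function(k)
        paste(sort(sample(cell_types, k)), collapse = ","), character(1))
    }
    sample_info <- do.call(rbind, lapply(cell_types, function(ct)
      data.frame(sample_id = paste0(ct, "_rep", seq_len(replicates[[ct]])),
                 cell_type = ct, replicate = seq_len(replicates[[ct]]),
                 stringsAsFactors = FALSE)))
    counts <- matrix(0, nrow = grid$n_bins, ncol = nrow(sample_info),
                     dimnames = list(NULL, sample_info$sample_id))
    peak_sets <- strsplit(peaks$cell_types, ",")
    for (s in seq_len(nrow(sample_info))) {
      ct <- sample_info$cell_type[s]
      lam <- rep(background_rate * depth, grid$n_bins)
      carried <- which(vapply(peak_sets, function(x) ct %in% x, logical(1)))
      peak_bins <- unlist(lapply(carried, function(i)
        peaks$start_bin[i]:peaks$end_bin[i]))
      if (noise_free) {
        v <- numeric(grid$n_bins)
        v[peak_bins] <- peak_rate * depth
        counts[, s] <- v
      } else {
        lam[peak_bins] <- lam[peak_bins] + peak_rate * depth
        counts[, s] <- stats::rpois(grid$n_bins, lam)
      }
    }
    truth <- structure(list(peaks = peaks, cell_types = cell_types,
                            seed = seed), class = "synthetic_truth")
    list(grid = grid, counts = counts, sample_info = sample_info,
         truth = truth)
  })
}

hwe_genotypes <- function(af, n) {
  g <- stats::rbinom(n, 1, af) + stats::rbinom(n, 1, af)
  c("0/0", "0/1", "1/1")[g + 1]
}

#' Simulate variant calls with a planted sharing-level enrichment
#'
#' Places SNVs inside panel bins at every sharing level (and outside the
#' panel at level 0) and assigns frequency classes so that the odds of a
#' variant being rare-or-novel rather than common rise linearly with
#' sharing level, from the baseline at level 1 up to `enrichment_fold`
#' times the baseline at the maximum level (`enrichment_fold = 1` is the
#' null). Per-sample genotypes carry DP/GQ and site MQ; a configurable
#' fraction of sites is given sub-threshold depth for filter testing.
#' The frequency reference covers the common and rare variants; novel
#' variants are absent from it.
#'
#' @param panel A `capture_panel`.
#' @param enrichment_fold Planted fold (>= 1).
#' @param n_per_level Expected variants per sharing level (and at level
#'   0).
#' @param n_samples Individuals genotyped.
#' @param base_noncommon_odds Baseline (rare+novel):common odds (default
#'   1/3).
#' @param rare_frac Fraction of non-common variants that are rare rather
#'   than novel (default 2/3).
#' @param qc_violation_frac Fraction of sites whose calls all receive
#'   DP = 5 (fails the depth filter; default 0).
#' @param genome Optional genome (`DNAStringSet`); reference alleles are
#'   read from it when supplied.
#' @param with_genotypes Emit per-sample genotypes (default TRUE; the
#'   variant table is identical either way, so calibration loops that
#'   only need sites can skip them).
#' @param seed Master seed.
#' @return List with `variants`, `genotypes`, `freq_ref`, `truth`.
#' @export
simulate_variants <- function(panel, enrichment_fold = 1,
                              n_per_level = 400, n_samples = 30,
                              base_noncommon_odds = 1 / 3,
                              rare_frac = 2 / 3,
                              qc_violation_frac = 0,
                              genome = NULL, with_genotypes = TRUE,
                              seed = 1) {
  if (enrichment_fold < 1)
    stop("enrichment_fold must be >= 1 (use 1 for null simulations)")
  if (!nrow(panel$bins)) stop("panel is empty")
  grid <- panel$grid
  K <- max(panel$bins$sharing)
  genome_chars <- if (!is.null(genome)) as_genome_strings(genome) else NULL
  with_substream(seed, "variants", {
    rows <- list()
    for (k in 0:K) {
      bins_k <- if (k == 0) {
        setdiff(seq_len(grid$n_bins), panel$bins$bin_id)
      } else panel$bins$bin_id[panel$bins$sharing == k]
      if (!length(bins_k)) next
      n_k <- stats::rpois(1, n_per_level)
      if (n_k == 0) next
      bsel <- sample(bins_k, n_k, replace = TRUE)
      iv <- bin_to_interval(grid, bsel)
      pos <- iv$start + sample.int(grid$bin_size, n_k, replace = TRUE)
      pos <- pmin(pos, grid$chrom_sizes[iv$chrom])
      odds <- base_noncommon_odds *
        (1 + (enrichment_fold - 1) * (max(k, 1) - 1) / max(K - 1, 1))
      p_noncommon <- odds / (1 + odds)
      noncommon <- stats::runif(n_k) < p_noncommon
      cls <- ifelse(!noncommon, "common",
                    ifelse(stats::runif(n_k) < rare_frac, "rare", "novel"))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = iv$chrom, pos = pos, level_truth = k,
        class_truth = cls, stringsAsFactors = FALSE)
    }
    v <- do.call(rbind, rows)
    # de-duplicate positions so (chrom, pos) identifies a site
    v <- v[!duplicated(paste(v$chrom, v$pos)), , drop = FALSE]
    n <- nrow(v)
    v$variant_id <- sprintf("var%05d", seq_len(n))
    if (!is.null(genome_chars)) {
      v$ref <- vapply(seq_len(n), function(i)
        substring(genome_chars[[v$chrom[i]]], v$pos[i], v$pos[i]),
        character(1))
    } else {
      v$ref <- sample(DNA, n, replace = TRUE)
    }
    v$alt <- vapply(v$ref, function(r) sample(setdiff(DNA, r), 1),
                    character(1))
    v$mq <- 60
    af <- ifelse(v$class_truth == "common", stats::runif(n, 0.01, 0.5),
          ifelse(v$class_truth == "rare", stats::runif(n, 5e-4, 0.0099),
                 NA))
    # conservation scores: planted to rise from common to novel
    shift <- c(common = 0, rare = 0.5, novel = 1)[v$class_truth]
    v$gerp <- stats::rnorm(n, shift, 1)
    v$cadd <- stats::rnorm(n, 5 + 5 * shift, 3)
    geno <- NULL
    qc_bad <- character(0)
    if (with_genotypes) {
      carrier_af <- ifelse(is.na(af), 1 / (2 * n_samples), af)
      m <- n * n_samples
      af_long <- rep(carrier_af, each = n_samples)
      dose <- stats::rbinom(m, 1, af_long) + stats::rbinom(m, 1, af_long)
      vid <- rep(v$variant_id, each = n_samples)
      # every non-common site must have at least one carrier
      carriers <- tapply(dose, vid, sum)[v$variant_id]
      fix <- v$variant_id[v$class_truth != "common" & carriers == 0]
      if (length(fix)) {
        at <- match(fix, v$variant_id)
        dose[(at - 1L) * n_samples + sample.int(n_samples, length(at),
                                                replace = TRUE)] <- 1L
      }
      gt <- c("0/0", "0/1", "1/1")[dose + 1]
      dp <- stats::rpois(m, 50) + 10L
      ad_ref <- integer(m)
      ad_ref[dose == 0] <- dp[dose == 0]
      ad_ref[dose == 2] <- stats::rbinom(sum(dose == 2), dp[dose == 2], 0.02)
      ad_ref[dose == 1] <- stats::rbinom(sum(dose == 1), dp[dose == 1], 0.5)
      geno <- data.frame(variant_id = vid,
                         sample = rep(sprintf("S%03d", seq_len(n_samples)), n),
                         gt = gt, dp = dp, gq = 99L, ad_ref = ad_ref,
                         stringsAsFactors = FALSE)
      if (qc_violation_frac > 0) {
        qc_bad <- sample(v$variant_id, round(qc_violation_frac * n))
        geno$dp[geno$variant_id %in% qc_bad] <- 5L
      }
    }
    freq_ref <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref,
                           alt = v$alt, af = af,
                           stringsAsFactors = FALSE)
    freq_ref <- freq_ref[!is.na(freq_ref$af), , drop = FALSE]
    truth <- structure(list(enrichment_fold = enrichment_fold,
                            classes = stats::setNames(v$class_truth,
                                                      v$variant_id),
                            levels = stats::setNames(v$level_truth,
                                                     v$variant_id),
                            qc_violations = qc_bad, seed = seed),
                       class = "synthetic_truth")
    list(variants = v[, c("variant_id", "chrom", "pos", "ref", "alt", "mq",
                          "gerp", "cadd", "level_truth", "class_truth")],
         genotypes = geno, freq_ref = freq_ref, truth = truth)
  })
}

pwm_consensus <- function(pwm) DNA[apply(pwm$probs, 2, which.max)]
pwm_anticonsensus <- function(pwm) DNA[apply(pwm$probs, 2, which.min)]

#' Simulate variants that create, disrupt, or spare TF motifs
#'
#' Builds a random genome with planted motif contexts and the variants
#' acting on them. "Create": the genome carries the motif consensus with
#' one substitution at a middle position, and the alternate allele
#' restores the consensus. "Disrupt": the genome carries the full
#' consensus and the alternate allele substitutes a low-probability
#' base. "Neutral": a random background position with a random
#' substitution. Planted sites are spaced so scan windows never overlap.
#'
#' @param pwms List of [new_pwm()] objects (assigned cyclically).
#' @param n_create,n_disrupt,n_neutral Event counts.
#' @param flank Scan flank the downstream classifier will use; motif
#'   widths must fit in the `2 * flank + 1` window.
#' @param seed Master seed.
#' @return List with `genome` (`DNAStringSet`, one chromosome),
#'   `variants` and `truth` (data.frame variant_id, pwm_id, event).
#' @export
simulate_motif_variants <- function(pwms, n_create, n_disrupt, n_neutral,
                                    flank = 15, seed = 1) {
  widths <- vapply(pwms, function(p) p$width, numeric(1))
  if (any(widths > 2 * flank + 1))
    stop("motif width exceeds the scan window")
  n <- n_create + n_disrupt + n_neutral
  spacing <- 2 * (2 * flank + 1) + max(widths)
  L <- (n + 2) * spacing
  genome <- make_genome(c(chrS = L), seed = substream_seed(seed, "motif_bg"))
  seq_chr <- as.character(genome[[1]])
  with_substream(seed, "motif_variants", {
    events <- sample(c(rep("created", n_create), rep("disrupted", n_disrupt),
                       rep("neutral", n_neutral)))
    anchors <- spacing * seq_len(n)
    rows <- list()
    for (i in seq_len(n)) {
      m <- ((i - 1) %% length(pwms)) + 1
      pwm <- pwms[[m]]
      w <- pwm$width
      mid <- (w + 1) %/% 2
      site_start <- anchors[i]  # 1-based start of planted site
      cons <- pwm_consensus(pwm)
      anti <- pwm_anticonsensus(pwm)
      vpos <- site_start + mid - 1
      if (events[i] == "created") {
        planted <- cons; planted[mid] <- anti[mid]
        substring(seq_chr, site_start, site_start + w - 1) <-
          paste(planted, collapse = "")
        ref <- anti[mid]; alt <- cons[mid]
      } else if (events[i] == "disrupted") {
        substring(seq_chr, site_start, site_start + w - 1) <-
          paste(cons, collapse = "")
        ref <- cons[mid]; alt <- anti[mid]
      } else {
        ref <- substring(seq_chr, vpos, vpos)
        alt <- sample(setdiff(DNA, ref), 1)
      }
      rows[[i]] <- data.frame(
        variant_id = sprintf("mv%04d", i), chrom = "chrS", pos = vpos,
        ref = ref, alt = alt,
        pwm_id = if (events[i] == "neutral") NA_character_ else pwm$id,
        event = events[i], stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    out_genome <- Biostrings::DNAStringSet(seq_chr)
    names(out_genome) <- "chrS"
    truth <- structure(list(events = tab[, c("variant_id", "pwm_id", "event")],
                            seed = seed), class = "synthetic_truth")
    list(genome = out_genome,
         variants = tab[, c("variant_id", "chrom", "pos", "ref", "alt")],
         truth = truth)
  })
}

#' Simulate simple gene models
#'
#' Places non-overlapping single-CDS transcripts (two isoforms per gene
#' when `isoforms = 2`) on the genome, with strand, TSS and a CDS whose
#' length is divisible by 3. Association p-values and normalized
#' coverage are attached so isoform filtering is exercised.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_genes Number of genes.
#' @param isoforms Isoforms per gene (default 1).
#' @param span Gene span in bp (default 2000).
#' @param cds_len CDS length in bp, divisible by 3 (default 300).
#' @param seed Master seed.
#' @return List with `transcripts` (transcript, gene, chrom, strand,
#'   start, end, tss, assoc_p, total_counts) and `cds` (exon table for
#'   [annotate_coding_effect()]).
#' @export
simulate_transcripts <- function(chrom_sizes, n_genes = 20, isoforms = 1,
                                 span = 2000, cds_len = 300, seed = 1) {
  if (cds_len %% 3 != 0) stop("cds_len must be divisible by 3")
  with_substream(seed, "transcripts", {
    per_chrom <- floor(chrom_sizes / (span * 2))
    slots <- rep(names(chrom_sizes), per_chrom)
    if (n_genes > length(slots)) stop("too many genes for the genome")
    pick <- sort(sample(length(slots), n_genes))
    rows <- list(); cds_rows <- list()
    for (gi in seq_len(n_genes)) {
      chrom <- slots[pick[gi]]
      idx <- sum(slots[seq_len(pick[gi])] == chrom)
      start <- (idx - 1) * span * 2 + span %/% 2
      strand <- sample(c("+", "-"), 1)
      for (iso in seq_len(isoforms)) {
        tx <- sprintf("g%03d.%d", gi, iso)
        cds_start <- start + 300 + (iso - 1) * 60
        rows[[length(rows) + 1]] <- data.frame(
          transcript = tx, gene = sprintf("g%03d", gi), chrom = chrom,
          strand = strand, start = start, end = start + span,
          tss = if (strand == "+") start + 1L else start + span,
          assoc_p = 10^(-stats::runif(1, 2, 12)),
          total_counts = stats::rpois(1, 300 + 200 * (iso == 1)),
          stringsAsFactors = FALSE)
        cds_rows[[length(cds_rows) + 1]] <- data.frame(
          tx_id = tx, chrom = chrom, strand = strand,
          start = cds_start, end = cds_start + cds_len,
          stringsAsFactors = FALSE)
      }
    }
    list(transcripts = do.call(rbind, rows), cds = do.call(rbind, cds_rows))
  })
}

#' Build a panel with a prescribed sharing architecture
#'
#' Constructs a capture panel directly from a target sharing-level
#' histogram, bypassing signal simulation: bins planted at level k are
#' assigned to k cell types. Useful as a fixed scaffold for variant
#' simulations where only the sharing annotation matters.
#'
#' @param grid A [bin_grid()].
#' @param bins_per_level Integer vector over levels 1..K: bins planted
#'   at each sharing level.
#' @param seed Master seed.
#' @return A `capture_panel` whose sharing histogram equals
#'   `bins_per_level`.
#' @export
synthetic_panel <- function(grid, bins_per_level, seed = 1) {
  K <- length(bins_per_level)
  with_substream(seed, "panel", {
    ids <- sample(grid$n_bins, sum(bins_per_level))
    level <- rep(seq_len(K), bins_per_level)
    # a bin at level k is carried by cell types 1..k
    sets <- lapply(seq_len(K), function(j) sort(ids[level >= j]))
    names(sets) <- paste0("CT", seq_len(K))
    build_panel(sets, grid)
  })
}

#' A sharply informative PWM
#'
#' Convenience constructor for simulations and examples: every column
#' puts probability `major` on the consensus base and splits the rest
#' evenly, giving a motif whose consensus is unambiguous and whose
#' single-mismatch sites score clearly lower.
#'
#' @param id Motif id.
#' @param consensus Consensus string over ACGT (its length is the
#'   width).
#' @param major Consensus base probability (default 0.91).
#' @return A [new_pwm()] object.
#' @export
informative_pwm <- function(id, consensus, major = 0.91) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  probs <- sapply(bases, function(b) {
    p <- rep((1 - major) / 3, 4)
    p[match(b, DNA)] <- major
    p
  })
  new_pwm(id, probs)
}

rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  shape <- (1 - rho) / rho
  p <- stats::rbeta(n, prob * shape, (1 - prob) * shape)
  stats::rbinom(n, size, p)
}

#' Effect size for a target share of allelic-imbalance variance
#'
#' Solves for the per-variant log2 effect beta such that the squared
#' Pearson correlation between the vicinity rare-variant count x (Poisson
#' with mean `count_lambda`) and the folded response `|s*beta*x + e|`
#' (random sign s, Gaussian noise e combining biological scatter and the
#' delta-method beta-binomial sampling noise) equals `target_r2`. This is
#' what the ordinary least squares R-squared estimates on the emitted
#' records.
#'
#' @param target_r2 Desired variance share in (0, 0.9).
#' @param count_lambda Poisson mean of the vicinity count.
#' @param total_reads Reads per record.
#' @param overdispersion Beta-binomial rho.
#' @param bio_sd Biological log2-ratio scatter.
#' @return Numeric beta (log2 fold per variant).
#' @export
ase_effect_for_r2 <- function(target_r2, count_lambda = 1,
                              total_reads = 500, overdispersion = 0.01,
                              bio_sd = 0.6) {
  n <- total_reads; rho <- overdispersion
  samp_var <- 4 * (1 + (n - 1) * rho) / (n * log(2)^2)
  sigma <- sqrt(bio_sd^2 + samp_var)
  xs <- 0:50
  wx <- stats::dpois(xs, count_lambda)
  r2_of <- function(beta) {
    mu <- beta * xs
    ey <- sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
      mu * (1 - 2 * stats::pnorm(-mu / sigma))
    ey2 <- mu^2 + sigma^2
    m_y <- sum(wx * ey)
    v_y <- sum(wx * ey2) - m_y^2
    m_x <- sum(wx * xs)
    cov_xy <- sum(wx * xs * ey) - m_x * m_y
    v_x <- sum(wx * xs^2) - m_x^2
    cov_xy^2 / (v_x * v_y)
  }
  stats::uniroot(function(b) r2_of(b) - target_r2, c(1e-6, 20))$root
}

#' Simulate haplotype-resolved allele counts with planted cis effects
#'
#' Per (transcript, individual) record the true log2 allelic ratio is a
#' per-variant effect times the number of qualifying rare variants the
#' individual carries near the transcript (random direction per
#' transcript), plus Gaussian biological scatter; allele counts are then
#' drawn beta-binomially around the implied allelic proportion. Common
#' eSNP genotypes are emitted per transcript so that homozygous
#' stratification is testable: heterozygous individuals receive an
#' additional common-variant effect that stratification removes.
#'
#' @param n_transcripts,n_individuals Problem size.
#' @param effect_size Planted log2 effect per rare variant (0 = null).
#' @param count_lambda Poisson mean of per-record rare-variant counts.
#' @param total_reads Mean reads per record.
#' @param overdispersion Beta-binomial rho (>= 0).
#' @param bio_sd Biological log2-ratio scatter (default 0.6).
#' @param common_effect Extra log2 effect in eSNP heterozygotes
#'   (default 0).
#' @param esnp_af Allele frequency of the common eSNP (default 0.3).
#' @param seed Master seed.
#' @return List with `records` (transcript, individual, count_a,
#'   count_b, n_snps, rare_count), `esnp_genotypes`, and `truth`.
#' @export
simulate_ase <- function(n_transcripts = 200, n_individuals = 1,
                         effect_size = 0, count_lambda = 1,
                         total_reads = 500, overdispersion = 0.01,
                         bio_sd = 0.6, common_effect = 0, esnp_af = 0.3,
                         seed = 1) {
  if (overdispersion < 0) stop("overdispersion must be >= 0")
  with_substream(seed, "ase", {
    tx <- sprintf("tx%04d", seq_len(n_transcripts))
    ind <- sprintf("I%03d", seq_len(n_individuals))
    rec <- expand.grid(transcript = tx, individual = ind,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(rec)
    sign_tx <- stats::setNames(sample(c(-1, 1), n_transcripts, TRUE), tx)
    rec$rare_count <- stats::rpois(n, count_lambda)
    esnp <- expand.grid(transcript = tx, individual = ind,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    esnp$gt <- hwe_genotypes(esnp_af, nrow(esnp))
    het <- esnp$gt[match(paste(rec$transcript, rec$individual),
                         paste(esnp$transcript, esnp$individual))] %in%
      c("0/1", "1/0")
    mu <- sign_tx[rec$transcript] * effect_size * rec$rare_count +
      ifelse(het, sample(c(-1, 1), n, TRUE) * common_effect, 0) +
      stats::rnorm(n, 0, bio_sd)
    p <- 2^mu / (1 + 2^mu)
    size <- stats::rpois(n, total_reads)
    size[size < 2] <- 2L
    count_a <- rbetabinom(n, size, p, overdispersion)
    rec$count_a <- count_a
    rec$count_b <- size - count_a
    rec$n_snps <- 1L + stats::rpois(n, 3)
    truth <- structure(list(effect_size = effect_size,
                            sign = sign_tx, common_effect = common_effect,
                            seed = seed), class = "synthetic_truth")
    list(records = rec, esnp_genotypes = esnp, truth = truth)
  })
}
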