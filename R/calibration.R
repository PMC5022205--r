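#' Type-I error of the sharing-level slope test under the null
#'
#' Repeatedly simulates variants with `enrichment_fold = 1` on a fixed
#' panel, runs the classification and sharing-level regression, and
#' reports how often the rare-plus-novel slope test rejects at `alpha`.
#' Under a calibrated test the rate is close to `alpha`.
#'
#' @param panel A `capture_panel` (held fixed across seeds).
#' @param n_seeds Number of simulation replicates.
#' @param alpha Nominal level (default 0.05).
#' @param n_per_level Expected variants per sharing level.
#' @param seed Master seed.
#' @return List with `rejection_rate` and the vector of p-values.
#' @export
calibrate_sharing_slope <- function(panel, n_seeds = 500, alpha = 0.05,
                                    n_per_level = 400, seed = 1) {
  p <- vapply(seq_len(n_seeds), function(i) {
    sim <- simulate_variants(panel, enrichment_fold = 1,
                             n_per_level = n_per_level,
                             with_genotypes = FALSE,
                             seed = substream_seed(seed, paste0("cal_sh", i)))
    cls <- classify_frequency(sim$variants, sim$freq_ref)
    lvl <- assign_dhs_sharing(sim$variants, panel)
    enr <- sharing_level_enrichment(cls, lvl)
    enr$fits$p_value[enr$fits$class_set == "rare_novel"]
  }, numeric(1))
  list(rejection_rate = mean(p < alpha), p_values = p)
}

#' Type-I error of the motif-proportion Fisher contrast under the null
#'
#' Draws per-variant motif-impact flags at a common rate for every
#' frequency class (no planted class effect) and reports how often the
#' common-vs-novel Fisher contrast rejects at `alpha`.
#'
#' @param n_seeds Replicates.
#' @param n_per_class Variants per class.
#' @param rate Common flag rate (default 0.1).
#' @param alpha Nominal level.
#' @param seed Master seed.
#' @return List with `rejection_rate` and the p-values.
#' @export
calibrate_motif_fisher <- function(n_seeds = 500, n_per_class = 1000,
                                   rate = 0.1, alpha = 0.05, seed = 1) {
  cls <- factor(rep(c("common", "rare", "novel"), each = n_per_class),
                levels = c("common", "rare", "novel"))
  p <- with_substream(seed, "cal_motif", {
    vapply(seq_len(n_seeds), function(i) {
      flag <- stats::rbinom(length(cls), 1, rate) == 1
      res <- impact_proportion_test(cls, flag)
      res$contrasts$p_value[res$contrasts$class_a == "common" &
                              res$contrasts$class_b == "novel"]
    }, numeric(1))
  })
  list(rejection_rate = mean(p < alpha), p_values = p)
}

#' Type-I error of the allelic-imbalance dose-response trend test
#'
#' Simulates allele counts with no planted cis effect and reports how
#' often the trend test of AI status on vicinity rare-variant count
#' rejects at `alpha`.
#'
#' @param n_seeds Replicates.
#' @param n_transcripts Records per replicate.
#' @param alpha Nominal level.
#' @param seed Master seed.
#' @return List with `rejection_rate` and the p-values.
#' @export
calibrate_ai_trend <- function(n_seeds = 500, n_transcripts = 400,
                               alpha = 0.05, seed = 1) {
  p <- vapply(seq_len(n_seeds), function(i) {
    sim <- simulate_ase(n_transcripts = n_transcripts, effect_size = 0,
                        seed = substream_seed(seed, paste0("cal_ai", i)))
    fd <- compute_fold_difference(sim$records$count_a, sim$records$count_b)
    keep <- !is.na(fd$fold) & fd$ai_class != "excluded"
    count_dose_response(fd$ai_class[keep] == "ai",
                        sim$records$rare_count[keep])$trend_p
  }, numeric(1))
  list(rejection_rate = mean(p < alpha, na.rm = TRUE), p_values = p)
}

#' Recover a planted sharing-level enrichment fold
#'
#' Simulates variants at the given planted fold and estimates it as the
#' rare-plus-novel to common odds at the maximum sharing level over the
#' same odds at level 1; the estimate is the geometric mean across
#' seeds.
#'
#' @param panel A `capture_panel`.
#' @param fold Planted fold.
#' @param n_seeds Replicates.
#' @param n_per_level Expected variants per level.
#' @param seed Master seed.
#' @return List with `estimate` and per-seed estimates.
#' @export
recover_enrichment_fold <- function(panel, fold = 3, n_seeds = 50,
                                    n_per_level = 400, seed = 1) {
  K <- max(panel$bins$sharing)
  est <- vapply(seq_len(n_seeds), function(i) {
    sim <- simulate_variants(panel, enrichment_fold = fold,
                             n_per_level = n_per_level,
                             with_genotypes = FALSE,
                             seed = substream_seed(seed, paste0("rec_f", i)))
    cls <- classify_frequency(sim$variants, sim$freq_ref)
    lvl <- assign_dhs_sharing(sim$variants, panel)
    odds_at <- function(k) {
      sum(cls %in% c("rare", "novel") & lvl == k) / sum(cls == "common" & lvl == k)
    }
    odds_at(K) / odds_at(1)
  }, numeric(1))
  list(estimate = exp(mean(log(est))), per_seed = est)
}

#' Recover a planted residual-variance share
#'
#' Simulates eSNP-homozygous ASE records whose planted per-variant
#' effect is calibrated (via [ase_effect_for_r2()]) to a target share of
#' variance of log2 fold difference explained by the vicinity
#' rare-variant count, then re-estimates that share with
#' [residual_variance_explained()].
#'
#' @param target_r2 Planted share.
#' @param n_records Records per replicate (default 5000).
#' @param n_seeds Replicates.
#' @param seed Master seed.
#' @return List with `estimate` (mean across seeds) and per-seed values.
#' @export
recover_residual_r2 <- function(target_r2 = 0.14, n_records = 5000,
                                n_seeds = 50, seed = 1) {
  beta <- ase_effect_for_r2(target_r2)
  est <- vapply(seq_len(n_seeds), function(i) {
    sim <- simulate_ase(n_transcripts = n_records, effect_size = beta,
                        seed = substream_seed(seed, paste0("rec_r2", i)))
    fd <- compute_fold_difference(sim$records$count_a, sim$records$count_b)
    residual_variance_explained(fd$fold, sim$records$rare_count)
  }, numeric(1))
  list(estimate = mean(est), per_seed = est, beta = beta)
}

#' Recover planted motif creation/disruption events
#'
#' Runs the scan-and-classify pipeline on simulated motif variants and
#' measures sensitivity (planted events called with the correct verdict
#' for their PWM) and the false-call rate on neutral variants (any
#' created or disrupted verdict for any PWM).
#'
#' @param pwms PWM library.
#' @param n_create,n_disrupt,n_neutral Event counts per replicate.
#' @param n_seeds Replicates.
#' @param family_alpha Family-wise level for the Bonferroni threshold
#'   over the scanned variants.
#' @param seed Master seed.
#' @return List with `sensitivity`, `false_call_rate`, per-seed values.
#' @export
recover_motif_events <- function(pwms, n_create = 20, n_disrupt = 20,
                                 n_neutral = 60, n_seeds = 10,
                                 family_alpha = 0.05, seed = 1) {
  sens <- fpr <- numeric(n_seeds)
  n_var <- n_create + n_disrupt + n_neutral
  alpha <- bonferroni_alpha(family_alpha, n_var)
  for (i in seq_len(n_seeds)) {
    sim <- simulate_motif_variants(pwms, n_create, n_disrupt, n_neutral,
                                   seed = substream_seed(seed,
                                                         paste0("rec_m", i)))
    res <- classify_motif_impact(sim$variants, sim$genome, pwms, alpha)
    ev <- sim$truth$events
    planted <- ev[ev$event != "neutral", , drop = FALSE]
    hit <- mapply(function(vid, pid, what) {
      any(res$calls$variant_id == vid & res$calls$pwm == pid &
            res$calls$verdict == what)
    }, planted$variant_id, planted$pwm_id, planted$event)
    sens[i] <- mean(hit)
    neutral <- ev$variant_id[ev$event == "neutral"]
    fl <- res$flags[res$flags$variant_id %in% neutral, ]
    fpr[i] <- mean(fl$any_created | fl$any_disrupted)
  }
  list(sensitivity = mean(sens), false_call_rate = mean(fpr),
       per_seed_sensitivity = sens, per_seed_false = fpr, alpha = alpha)
}

#' Recover a planted peak architecture exactly (noise-free)
#'
#' Runs the full panel design on a deterministic (noise-free) simulated
#' experiment and checks that every planted peak bin appears in the
#' panel with sharing level equal to its planted cell-type count and
#' that no unplanted bin enters the panel.
#'
#' @param n_cell_types Number of cell types.
#' @param replicates Replicates per cell type.
#' @param peaks_per_level Planted peaks per sharing level.
#' @param seed Master seed.
#' @return List with `exact` (logical), `panel`, `truth`.
#' @export
recover_peak_architecture <- function(n_cell_types = 4, replicates = 2,
                                      peaks_per_level = c(3, 3, 3, 3),
                                      seed = 1) {
  cts <- paste0("CT", seq_len(n_cell_types))
  sim <- simulate_dhs_experiments(
    c(chrA = 2e5, chrB = 1e5), cts,
    stats::setNames(rep(replicates, n_cell_types), cts),
    peaks_per_level = peaks_per_level, noise_free = TRUE, seed = seed)
  peak_bins_per_ct <- lapply(cts, function(ct) {
    sel <- vapply(strsplit(sim$truth$peaks$cell_types, ","),
                  function(x) ct %in% x, logical(1))
    unlist(mapply(seq, sim$truth$peaks$start_bin[sel],
                  sim$truth$peaks$end_bin[sel], SIMPLIFY = FALSE))
  })
  n_top <- sum(lengths(peak_bins_per_ct))
  tracks <- lapply(seq_len(nrow(sim$sample_info)), function(s)
    bin_and_normalize(sim$counts[, s], sim$grid,
                      sample_id = sim$sample_info$sample_id[s],
                      cell_type = sim$sample_info$cell_type[s]))
  panel <- design_panel(tracks, sim$grid, n_top = n_top,
                        include_zero = FALSE)
  expected <- table(unlist(peak_bins_per_ct))
  expected <- data.frame(bin_id = as.integer(names(expected)),
                         sharing = as.integer(expected))
  expected <- expected[order(expected$bin_id), ]
  rownames(expected) <- NULL
  exact <- identical(expected$bin_id, panel$bins$bin_id) &&
    identical(expected$sharing, panel$bins$sharing)
  list(exact = exact, panel = panel, truth = sim$truth)
}
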