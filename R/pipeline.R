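#' Default pipeline configuration
#'
#' All tunable parameters with their study-design defaults (100-bp bins,
#' top-bin cut, 50%-consensus, exome-overlap 0.5, QC DP>=10 GQ>=70
#' MQ>=50 AB 0.10-0.90, MAF 1%, scan flank 15, family alpha 0.05,
#' vicinity 20 kb, AI band 2-9 fold, equal <= 1.5) and the scaled problem
#' sizes used for the bundled synthetic world.
#'
#' @param seed Master seed.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    stages = list(simulate = TRUE, design = TRUE, enrich = TRUE,
                  annotate = TRUE, motif = TRUE, ase = TRUE),
    simulate = list(
      chrom_sizes = c(chrA = 2e5, chrB = 1e5),
      cell_types = paste0("CT", 1:4),
      replicates = c(CT1 = 2, CT2 = 2, CT3 = 2, CT4 = 1),
      peaks_per_level = c(6, 6, 6, 6),
      background_rate = 1, peak_rate = 50, depth = 1),
    design = list(bin_size = 100, n_top = 120, block_size = NULL,
                  min_overlap = 0.5, exome_min_frac = 0.5),
    enrich = list(n_hits = 40, iterations = 200),
    annotate = list(enrichment_fold = 2, n_per_level = 150, n_samples = 10,
                    dp_min = 10, gq_min = 70, mq_min = 50,
                    ab_range = c(0.10, 0.90), maf_common = 0.01),
    motif = list(consensus = c("TGACGT", "CCGGAA", "CACGTG"),
                 n_create = 10, n_disrupt = 10, n_neutral = 30,
                 family_alpha = 0.05, flank = 15),
    ase = list(n_transcripts = 300, effect_size = 0.6,
               overdispersion = 0.01, total_reads = 500))
}

stage_files <- function(dir) list.files(dir, recursive = TRUE,
                                        full.names = TRUE)

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in dependency order (simulate, design,
#' enrich, annotate, motif, ase), writing each stage's tables under
#' `out_dir` together with the resolved configuration and a manifest
#' (stage list, seed, file digests). Reruns with an identical
#' configuration are byte-identical.
#'
#' @param config Configuration from [default_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stages_run <- character(0)
  cs <- config$simulate$chrom_sizes

  genome <- make_genome(cs, seed = seed)
  sim <- simulate_dhs_experiments(
    cs, config$simulate$cell_types, config$simulate$replicates,
    peaks_per_level = config$simulate$peaks_per_level,
    background_rate = config$simulate$background_rate,
    peak_rate = config$simulate$peak_rate,
    depth = config$simulate$depth, bin_size = config$design$bin_size,
    seed = seed)
  if (isTRUE(config$stages$simulate)) {
    Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"))
    write_chrom_sizes(cs, file.path(out_dir, "chrom.sizes"))
    for (s in seq_len(nrow(sim$sample_info)))
      write_bedgraph(sim$counts[, s], sim$grid,
                     file.path(out_dir, paste0(
                       sim$sample_info$sample_id[s], ".bedGraph")))
    write_truth(sim$truth, file.path(out_dir, "dhs_truth.json"))
    stages_run <- c(stages_run, "simulate")
  }

  tracks <- lapply(seq_len(nrow(sim$sample_info)), function(s)
    bin_and_normalize(sim$counts[, s], sim$grid,
                      sample_id = sim$sample_info$sample_id[s],
                      cell_type = sim$sample_info$cell_type[s]))
  panel <- design_panel(tracks, sim$grid, n_top = config$design$n_top,
                        block_size = config$design$block_size,
                        min_overlap = config$design$min_overlap)
  if (isTRUE(config$stages$design)) {
    write_panel_bed(panel, file.path(out_dir, "panel.bed"))
    utils::write.table(attr(panel, "report"),
                       file.path(out_dir, "design_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages_run <- c(stages_run, "design")
  }

  if (isTRUE(config$stages$enrich)) {
    hits <- with_substream(seed, "hits", {
      n <- config$enrich$n_hits
      inside <- sample(panel$bins$bin_id, ceiling(n / 2), replace = TRUE)
      outside <- sample(setdiff(seq_len(sim$grid$n_bins), panel$bins$bin_id),
                        floor(n / 2))
      iv <- bin_to_interval(sim$grid, c(inside, outside))
      data.frame(id = sprintf("rs%04d", seq_len(n)), chrom = iv$chrom,
                 pos = iv$start + sample.int(sim$grid$bin_size, n,
                                             replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    cf <- capture_fraction(hits, panel)
    nulls <- sample_random_bins(seq_len(sim$grid$n_bins),
                                nrow(panel$bins),
                                iterations = config$enrich$iterations,
                                seed = seed)
    null_ov <- vapply(nulls, function(b) hits_in_bins(hits, b, sim$grid),
                      numeric(1))
    emp <- empirical_enrichment(cf$n_captured, null_ov)
    utils::write.table(
      data.frame(n_hits = cf$n_total, captured = cf$n_captured,
                 fraction = cf$fraction, fold = emp$fold,
                 p_empirical = emp$p_value),
      file.path(out_dir, "enrichment.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    stages_run <- c(stages_run, "enrich")
  }

  txs <- simulate_transcripts(cs, n_genes = 20, isoforms = 2, seed = seed)
  if (isTRUE(config$stages$annotate)) {
    an <- config$annotate
    vs <- simulate_variants(panel, enrichment_fold = an$enrichment_fold,
                            n_per_level = an$n_per_level,
                            n_samples = an$n_samples,
                            qc_violation_frac = 0.05,
                            genome = genome, seed = seed)
    write_vcf(vs$variants, vs$genotypes, file.path(out_dir, "variants.vcf"))
    utils::write.table(vs$freq_ref, file.path(out_dir, "freq_ref.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    qc <- qc_filter(vs$variants, vs$genotypes, an$dp_min, an$gq_min,
                    an$mq_min, an$ab_range)
    v <- qc$variants
    v$class <- classify_frequency(v, vs$freq_ref, maf_common = an$maf_common)
    v$effect <- annotate_coding_effect(v, txs$cds, genome)
    v$sharing <- assign_dhs_sharing(v, panel)
    enr <- sharing_level_enrichment(v$class, v$sharing)
    utils::write.table(v, file.path(out_dir, "variants_annotated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr$table, file.path(out_dir, "sharing_folds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(variant_summary_table(v$class, v$effect, v$sharing),
                       file.path(out_dir, "variant_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages_run <- c(stages_run, "annotate")
  }

  if (isTRUE(config$stages$motif)) {
    mo <- config$motif
    pwms <- lapply(seq_along(mo$consensus), function(i)
      informative_pwm(paste0("M", i), mo$consensus[i]))
    write_meme(pwms, file.path(out_dir, "motifs.meme"))
    msim <- simulate_motif_variants(pwms, mo$n_create, mo$n_disrupt,
                                    mo$n_neutral, flank = mo$flank,
                                    seed = seed)
    alpha <- bonferroni_alpha(mo$family_alpha, nrow(msim$variants))
    res <- classify_motif_impact(msim$variants, msim$genome, pwms, alpha,
                                 flank = mo$flank)
    utils::write.table(res$calls, file.path(out_dir, "motif_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_truth(msim$truth, file.path(out_dir, "motif_truth.json"))
    stages_run <- c(stages_run, "motif")
  }

  if (isTRUE(config$stages$ase)) {
    ae <- config$ase
    asim <- simulate_ase(n_transcripts = ae$n_transcripts,
                         effect_size = ae$effect_size,
                         overdispersion = ae$overdispersion,
                         total_reads = ae$total_reads, seed = seed)
    fd <- compute_fold_difference(asim$records$count_a, asim$records$count_b)
    rec <- cbind(asim$records, fd)
    utils::write.table(rec, file.path(out_dir, "ase_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    keep <- !is.na(rec$fold) & rec$ai_class != "excluded"
    dr <- count_dose_response(rec$ai_class[keep] == "ai",
                              rec$rare_count[keep], rec$n_snps[keep])
    utils::write.table(dr$table, file.path(out_dir, "ase_dose_response.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages_run <- c(stages_run, "ase")
  }

  files <- stage_files(out_dir)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(stages = stages_run, seed = seed,
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
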