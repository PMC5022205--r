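#!/usr/bin/env Rscript
# Stage 1: build the synthetic study world.
#
# Generates a small two-chromosome genome, replicated DNase-I
# hypersensitivity experiments for four immune-like cell types with a
# planted peak architecture (six peaks at each sharing level 1..4), and
# writes every downstream input to results/data/: genome FASTA,
# chrom.sizes, one bedGraph per sample, and the ground-truth JSON.

suppressMessages(library(regcapture))

seed <- 42
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

chrom_sizes <- c(chrA = 2e5, chrB = 1e5)
cell_types <- paste0("CT", 1:4)
replicates <- c(CT1 = 3, CT2 = 2, CT3 = 2, CT4 = 1)

genome <- make_genome(chrom_sizes, seed = seed)
Biostrings::writeXStringSet(genome, file.path(out, "genome.fa"))
write_chrom_sizes(chrom_sizes, file.path(out, "chrom.sizes"))

sim <- simulate_dhs_experiments(chrom_sizes, cell_types, replicates,
                                peaks_per_level = c(6, 6, 6, 6),
                                background_rate = 1, peak_rate = 50,
                                seed = seed)
for (s in seq_len(nrow(sim$sample_info)))
  write_bedgraph(sim$counts[, s], sim$grid,
                 file.path(out, paste0(sim$sample_info$sample_id[s],
                                       ".bedGraph")))
write.table(sim$sample_info, file.path(out, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_truth(sim$truth, file.path(out, "dhs_truth.json"))

cat("samples written:", nrow(sim$sample_info), "\n")
cat("planted peaks per sharing level:\n")
print(table(sim$truth$peaks$level))
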