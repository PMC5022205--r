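#!/usr/bin/env Rscript
# Stage 2: design the capture panel from the simulated DNase-I signal.
#
# Reads the per-sample bedGraphs back from disk, normalizes reads per
# 100-bp bin by library size, ranks bins per sample, takes the
# replicate consensus within each cell type, and merges across cell
# types with per-bin sharing levels. The planted peak architecture from
# stage 1 should be recovered: the sharing histogram of the panel is
# compared against the truth. Writes panel.bed (4th column = sharing
# level) and the per-cell-type design report.

suppressMessages(library(regcapture))

data_dir <- "results/data"
samples <- read.table(file.path(data_dir, "samples.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
sizes <- read.table(file.path(data_dir, "chrom.sizes"), sep = "\t")
grid <- bin_grid(stats::setNames(sizes$V2, sizes$V1), 100)

tracks <- lapply(seq_len(nrow(samples)), function(s) {
  bg <- read_bedgraph(file.path(data_dir, paste0(samples$sample_id[s],
                                                 ".bedGraph")), grid)
  bin_and_normalize(bg, grid, sample_id = samples$sample_id[s],
                    cell_type = samples$cell_type[s])
})

# 48 planted peak bins per cell type at most; keep a margin above that
panel <- design_panel(tracks, grid, n_top = 120)
write_panel_bed(panel, "results/panel.bed")
write.table(attr(panel, "report"), "results/design_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read_truth(file.path(data_dir, "dhs_truth.json"))
peak_bins <- unlist(mapply(seq, truth$peaks$start_bin, truth$peaks$end_bin,
                           SIMPLIFY = FALSE))
recovered <- mean(peak_bins %in% panel$bins$bin_id)

cat("panel:", nrow(panel$bins), "bins,", panel$total_target_bp, "bp\n")
cat("planted peak bins recovered:", sprintf("%.1f%%", 100 * recovered), "\n")
cat("sharing histogram (panel):\n"); print(table(panel$bins$sharing))
cat("sharing histogram (truth, peak bins x width):\n")
print(table(rep(truth$peaks$level,
                truth$peaks$end_bin - truth$peaks$start_bin + 1)))
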