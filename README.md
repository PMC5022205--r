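# regcapture

Most GWAS signals for immune-mediated disease fall in non-coding DNA, in
regulatory elements that are open chromatin in immune cells. A targeted
capture panel built from DNase I hypersensitive sites (DHSs) makes it
affordable to re-sequence exactly those regions deeply enough to call
rare and novel variants with confidence, and haplotype-resolved RNA-seq
(allele-specific expression, ASE) then asks whether those variants
actually perturb gene expression in *cis*.

`regcapture` implements that whole computational arc as a tested R
package, exercised end to end on synthetic data with planted ground
truth:

- **Panel design** — genome binned at 100 bp; per-sample signal
  `reads in bin / total reads`; top-*N* bins per sample; rank blocks
  dropped when mean pairwise overlap between replicates falls below
  50%; replicate consensus (≥ 50% of samples, both of two, or the
  single sample); bins ≥ 50% covered by exome targets removed; merged
  intervals annotated with the **sharing level** (number of cell types
  whose consensus contains the bin).
- **Capture enrichment** — fraction of lead SNPs captured directly or
  via an LD proxy; empirical nulls from random bin draws
  (`p = (1 + #{null ≥ obs}) / (1 + iterations)`); two-sided Fisher
  exact tests by hypergeometric enumeration.
- **Variant annotation** — genotype-level QC (DP ≥ 10, GQ ≥ 70,
  MQ ≥ 50, heterozygous reference-allele balance in 10–90%); frequency
  classes (common: MAF ≥ 1%; rare: catalogued, MAF < 1%; novel: absent
  from the catalogues); codon-level coding effects; fold enrichment of
  rare+novel vs common variants across sharing levels with an OLS
  trend test.
- **Motif impact** — log-odds PWM scanning of both alleles within
  ±15 nt (both strands, placements overlapping the variant), p-values
  from a dynamic-programming score distribution, Bonferroni threshold
  `0.05 / n variants`; a motif is *created* if only the alternate
  allele is significant, *disrupted* if only the reference allele is.
- **ASE analysis** — fold difference = higher/lower allele count
  (equal ≤ 1.5; AI 2–9; > 9 excluded as imprinting/artefact);
  SNP-count-adjusted AI proportions; vicinity (±20 kb) variant counts;
  promoter–DHS correlation links; homozygous-eSNP stratification;
  dose–response trend; residual variance of log2 fold explained by the
  rare-variant count (R²).
- **Synthetic data** — every input (genome, DHS bedGraphs, VCF,
  frequency reference, PWMs, allele counts) generated with planted
  effect sizes, so each statistic above can be checked against truth.

## Worked example

Design a panel from simulated replicated DNase experiments and check it
against the planted peak architecture:

```r
library(regcapture)

sim <- simulate_dhs_experiments(
  c(chrA = 2e5, chrB = 1e5), cell_types = paste0("CT", 1:4),
  replicates = c(CT1 = 3, CT2 = 2, CT3 = 2, CT4 = 1),
  peaks_per_level = c(6, 6, 6, 6), seed = 42)

tracks <- lapply(seq_len(nrow(sim$sample_info)), function(s)
  bin_and_normalize(sim$counts[, s], sim$grid,
                    cell_type = sim$sample_info$cell_type[s]))
panel <- design_panel(tracks, sim$grid, n_top = 120)
panel
#> capture_panel: 159 bins in 126 merged intervals, 15900 bp; 4 cell types (max sharing 4)
table(panel$bins$sharing)
#>   1   2   3   4
#> 121  14  12  12
```

Every planted peak bin is recovered at its planted sharing level (the
extra level-1 bins are top-ranked background, dominated by the
single-replicate cell type — the price the real design pays for
single-sample cell types too). The same workflow, continued through
variant annotation and ASE, is laid out as numbered scripts under
`analysis/`; run them in order from the repository root:

```sh
Rscript analysis/01_simulate_inputs.R     # synthetic genome + DNase tracks
Rscript analysis/02_design_panel.R        # panel + sharing histogram vs truth
Rscript analysis/03_capture_enrichment.R  # SNP capture + random-bin nulls
Rscript analysis/04_annotate_variants.R   # QC, classes, sharing-level slopes
Rscript analysis/05_motif_impact.R        # motif creation/disruption calls
Rscript analysis/06_ase_analysis.R        # allelic imbalance + R²
```

Each script states what it found on stdout and writes its tables under
`results/`. Stage 4, for example, fits the fold-enrichment regression
across sharing levels on a planted two-fold enrichment and prints

```
sharing-level enrichment slopes:
  class_set      slope      p_value
       rare 0.04171875 1.428398e-02
      novel 0.08577672 4.208241e-07
 rare_novel 0.05634963 3.860298e-04
```

— rare and novel variants concentrate in DHSs shared across more cell
types, which is the package's core biological readout.

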