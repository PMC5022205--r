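---
title: "Methods: regulatory capture design and rare-variant functional analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory capture design and rare-variant functional analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regcapture)
```

## The problem

Regulatory variation in immune cells is concentrated in DNase I
hypersensitive sites (DHSs). `regcapture` implements the computational
side of a capture-and-resequence strategy for those sites: design a
targeted panel from DNase signal across immune cell types, then
characterise the variants such a panel yields — their frequency
spectrum, their concentration in widely shared (more active) DHSs,
their effect on transcription-factor motifs, and their association with
allele-specific expression (ASE). Because the original inputs are
consortium-scale datasets, the package ships a synthetic-data module
that emulates their statistical structure with planted, recoverable
effect sizes; every analysis is validated against that ground truth.

## Panel design

The genome is tiled into 100-bp bins (0-based half-open internally and
in BED output; VCF positions are 1-based at I/O boundaries). Per
sample, signal is reads-in-bin divided by total reads, a library-size
normalization that makes ranks comparable across samples. The design
then proceeds per cell type:

1. **Top-bin cut** (`n_top`): the highest-signal bins per sample. The
   full-scale design value of 300,000 bins of 100 bp is about 1% of the
   human genome; scaled examples keep `n_top` a similar small multiple
   of the planted open-chromatin fraction. Ties are broken by genomic
   order (chromosome, then start), so zero-signal bins are rankable and
   the cut is always met; `include_zero = FALSE` truncates at the last
   nonzero bin instead, which is what exact noise-free recovery tests
   use.
2. **Rank-block concordance** (`block_size`, `min_overlap = 0.5`):
   consecutive rank strata are dropped when replicate agreement decays.
   The overlap statistic is the mean over sample pairs of
   |intersection| / block size, comparing blocks at the same rank
   range. The metric was an open choice (pairwise vs pooled, Jaccard vs
   containment); the mean pairwise containment is symmetric in samples,
   bounded in [0, 1], and exactly 1 for identical blocks. Single-sample
   cell types retain all strata — there is no pair to compare.
3. **Replicate consensus**: with `m >= 3` samples a bin must appear in
   `ceiling(m/2)` of them; with two samples, in both; a single sample
   stands alone. Block filtering is applied before consensus within a
   cell type; the opposite order is representable by calling the
   operations directly.
4. **Exome subtraction** (`min_frac = 0.5`): a bin is removed when at
   least half its length is covered by the union of exome capture
   targets (overlapping exome records are unioned first so
   double-covered bp count once).
5. **Merge and sharing**: the union of per-cell-type sets is merged
   into maximal intervals; each bin's **sharing level** is the number
   of cell types whose consensus contains it (1..K).

The whole design is deliberately a composition of set operations, so a
naive reference implementation that materializes every set explicitly
can check it bin for bin; the test suite and the acceptance script both
do this on grids of a few thousand bins.

## Capture enrichment

A lead SNP is captured if its own position or any LD proxy (proxy
tables are inputs; computing r² is out of scope) lies in a panel
interval. Enrichment against chance uses two routes: an empirical null
of random bin sets of matching size (add-one estimator,
`p = (1 + #{null >= obs}) / (1 + iterations)`, so p is never exactly 0
and the floor at 1000 iterations is 1/1001), and a two-sided Fisher
exact test computed by direct enumeration of the conditional
hypergeometric distribution (all tables with probability at most that
of the observed one, with the customary `1 + 1e-7` tie tolerance). The
odds ratio reported is the sample odds ratio `ad/bc`, with an infinity
sentinel when `bc = 0` — not the conditional MLE that `fisher.test`
prints; `fisher.test` serves as an independent oracle for the p-value
in the tests.

## Variant annotation

QC follows fixed thresholds per genotype call: depth ≥ 10, genotype
quality ≥ 70, site mapping quality ≥ 50, and for heterozygous calls a
reference-read fraction within 10–90%. The allele-balance rule is
applied to heterozygotes only — homozygous-alternate calls would almost
never satisfy it, and it exists to catch allelic bias, which only
heterozygotes can show. Missing required fields fail the call (logged),
indel records are excluded, and a site survives if any call passes;
filtering is idempotent.

Frequency classes partition QC-passing SNVs: **common** (reference MAF
≥ 1%), **rare** (catalogued with MAF < 1%), **novel** (absent from the
frequency reference and the known-sites list). Reference allele
frequencies are folded to minor-allele frequencies before thresholding.
Matching requires identical chrom/pos/ref/alt; a position match with a
different alternate allele is treated as novel at the allele level.

Coding effects translate the codon containing the variant for both
alleles (strand-aware) and compare amino acids; a variant whose stated
reference base disagrees with the genome is rejected and logged rather
than silently reinterpreted.

The sharing-level analysis computes, per level *k*,

fold(k) = [ (rare+novel)_k / common_k ] / [ (rare+novel)_DHS / common_DHS ],

then fits an unweighted OLS line of fold on level and reports the
two-sided t-test on the slope. Levels with no common variants are
omitted with a warning (the fold is undefined there). Unweighted OLS
was a declared choice; the per-level counts in both the study-scale and
simulated settings are of comparable magnitude, which is what makes the
equal-weight fit and its t-test approximately calibrated — the
simulator places equal expected numbers of variants at every level for
exactly this reason.

## Motif impact

Scanning is a self-contained reimplementation of the standard log-odds
PWM scan: probabilities get a total pseudocount mass of 0.01
distributed by the background (uniform by default), scores are
`log2(p/background)` summed over positions, and every placement on both
strands whose footprint covers the variant is evaluated for each
allele; the best placement's p-value is compared to a Bonferroni
threshold `family_alpha / n_variants` (corrected over variants scanned,
not variants × PWMs — the study's convention; configurable). *Created*
means only the alternate allele is significant; *disrupted*, only the
reference; significance for both yields `none` and the score change is
still reported.

P-values come from a dynamic-programming score distribution: per-cell
scores are rounded to a common unit and convolved across positions
under the background. Two numerical choices matter:

- **Resolution.** The unit is the attainable score range divided by
  500,000. Coarse discretization is not a small-error regime here: a
  single w-mer classified to the wrong side of a threshold shifts the
  p-value by that w-mer's entire background mass (6% for a width-2
  motif), so the resolution must separate distinct attained scores by
  more than the accumulated rounding slack. At this resolution the DP
  tail matches exhaustive 4^w enumeration to better than 1e-3 for all
  widths up to 8, the remaining discrepancies being genuine near-ties.
- **Query slack.** A raw query score is mapped to its integer bin minus
  the worst-case accumulated rounding slack (⌊w/2⌋ + 1 units), which
  guarantees a w-mer attaining exactly the queried score is counted in
  its own tail; the estimate errs, if at all, conservatively (p no
  smaller than exact). Monotonicity — higher score, no larger p — is
  preserved.

## ASE analysis

Fold difference is the higher allele count over the lower, so 1 means
balanced expression; classes are equal (≤ 1.5), intermediate, AI
(2–9), and excluded (> 9, enriched for imprinting and technical
artefacts; excluded records leave all enrichment denominators). When
one count is zero a pseudocount of 1 is added to both alleles
(configurable to dropping the record); double zeros are dropped.

The rare-variant signal is quantified by:

- **Adjusted AI proportions** across nested fold bands `[L, 9]` for
  L = 1.5..3.5. Transcripts with more informative SNPs are better
  powered and overrepresented at high AI, so the raw proportion is
  rescaled multiplicatively by (grand mean SNPs / band mean SNPs). The
  covariate was named in the source design but not the functional
  form; the multiplicative rescaling is exact identity when SNP counts
  are constant, which the tests assert.
- **Vicinity counts** in the closed window [gene start − 20 kb, gene
  end + 20 kb], the gene span being that of the kept isoform (best
  covered isoform among transcripts with association p < 1e-5, strict
  inequality at the boundary).
- **AI enrichment**, P(carrier | AI) / P(carrier | all tested), per
  predicate (coding, non-coding vicinity, promoter-linked DHS at each
  correlation threshold, Hi-C-linked). Across correlation thresholds
  the linked-DHS sets are nested, so the per-threshold folds are
  correlated; the OLS slope over thresholds is reported as a
  descriptive trend with that caveat, and the **dose–response trend
  test** (Cochran–Armitage style, AI status on vicinity rare-variant
  count) is the calibrated test used in null-calibration checks.
- **Homozygous-eSNP stratification**: restricting to individuals
  homozygous at a transcript's top common eSNP removes the
  common-variant contribution to AI; transcripts without an eSNP
  annotation are excluded from the stratified subset.
- **Residual variance explained**: R² from OLS of log2 fold on the
  rare+novel vicinity count over eSNP-homozygous records. The source
  analysis reported a headline share without a printed formula; this
  operationalization — squared correlation on the folded log scale
  among homozygotes — is the package's declared definition, and the
  generator plants effects calibrated to a target value of exactly
  this quantity.

## The synthetic-data module

The generator defines the study conditions; it is not a tuning knob.

- **DHS counts**: Poisson background (mean 1 read/bin) plus Poisson
  peak signal (mean 50) at planted peaks, independent across
  replicates; a `noise_free` mode makes counts deterministic so design
  recovery can be asserted exactly. Peaks carry explicit cell-type
  subsets, so the panel's sharing histogram has a known target.
- **Variants**: placed uniformly within bins at each sharing level
  (equal expected counts per level), with the odds of being
  rare-or-novel rising linearly from the baseline (default 1:3) at
  level 1 to `enrichment_fold` times the baseline at level K;
  `enrichment_fold = 1` is the exact null. Common allele frequencies
  are Uniform(0.01, 0.5), rare Uniform(5e-4, 0.0099), novel absent
  from the reference with one guaranteed carrier. Genotypes follow
  Hardy–Weinberg; depth is Poisson(50)+10, GQ 99, MQ 60, and a
  configurable fraction of sites gets DP = 5 to exercise the filter.
  Conservation scores shift upward from common to novel so the
  constraint contrasts have signal.
- **ASE counts**: beta-binomial around the allelic proportion implied
  by a true log2 ratio = (random per-transcript sign) × effect ×
  vicinity rare count + Gaussian biological scatter, with an optional
  extra effect in eSNP heterozygotes so stratification has something
  to remove. Defaults — biological scatter 0.6 log2 units,
  overdispersion ρ = 0.01, ~500 reads per record, Poisson(1) vicinity
  counts — were fixed once as realistic study conditions: they put
  roughly a sixth of null transcripts past the 2-fold AI bound,
  leaving all AI classes populated, and give the trend tests
  well-behaved event counts. For a target variance share v,
  `ase_effect_for_r2()` inverts the squared correlation of the folded
  response analytically (folded-normal moments over the Poisson count
  distribution, with the beta-binomial sampling variance entering via
  the delta method) rather than by trial simulation.
- **Motif variants**: planted sites are the PWM consensus with (create)
  or without (disrupt) a single substitution at the central motif
  position, using the lowest-probability base so the score gap is
  maximal; neutral variants are random substitutions in background
  sequence. Sites are spaced beyond the scan window so events cannot
  interact. With the sharply informative default PWMs (consensus
  probability 0.91), the consensus p-value sits well below and the
  one-mismatch p-value well above the Bonferroni threshold for a
  100-variant scan family, which is what makes the planted verdicts
  recoverable.
- **Reproducibility**: all randomness flows from one master seed
  through named substreams (a polynomial string hash folded into the
  seed), so regenerating one output never perturbs another and
  identical configurations are byte-identical; the pipeline manifest
  records file digests to make this checkable.

What the generator does **not** emulate: mappability and GC structure
in DNase signal, LD between variants, haplotype phasing error,
reference-mapping bias in allele counts, multi-allelic sites, indels,
and sequencing error in the genome itself. Passing tests therefore
demonstrate that the statistics recover what was planted under clean
sampling noise — not that the pipeline is robust to alignment-level
artefacts, which the surrounding (out-of-scope) upstream tools are
responsible for.

## Problem sizes and calibration design

The bundled analyses and checks run at desk scale by choice: grids of a
few thousand bins, panels of ~500 bins across 12 sharing levels,
~5,000 variants or ASE records per simulation, 500 seeds for type-I
error estimates, and 10–30 seeds for recovery experiments. At these
sizes the whole test suite and the acceptance script each run in a few
minutes on one CPU, while every estimator is still in the regime where
its asymptotic test is meaningful (for instance, ~400 variants per
sharing level keep the fold ratios approximately normal, and the
rejection-rate standard error at 500 seeds is under 0.01).

Null calibration checks simulate with every planted effect set to
neutral and verify that the sharing-level slope test, the
motif-proportion Fisher contrast, and the dose–response trend test
reject at the nominal 5% level. The Fisher contrast is checked at the
flag level (class labels exchangeable by construction) because the
scanning stage upstream of the flags is deterministic given the
sequence and cannot break exchangeability between frequency classes.

## Known limitations

- The promoter–DHS correlation trend (Fig-3b-style fold vs r
  threshold) has no calibrated p-value by construction (nested sets);
  it is reported descriptively.
- The coding-effect annotator handles biallelic SNVs on single- or
  multi-exon CDS models with CDS length divisible by 3; splice-site
  and UTR effects are out of scope, as are indels throughout.
- Fisher enumeration is exact but O(support) per table; for the very
  large counts of a full-scale study the normal approximation would be
  preferable, though at panel scale this never matters.
- `capture_panel` objects keep per-bin sharing in memory; at the full
  human-genome scale (~30M bins) a run-length representation would be
  needed.
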