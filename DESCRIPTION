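Package: regcapture
Title: Regulatory-Region Capture Panel Design and Rare-Variant Functional Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs a targeted capture panel for regulatory regions from
    per-sample DNase-I hypersensitivity signal (100-bp binning, top-bin
    ranking, replicate consensus, rank-block concordance filtering, exome
    subtraction, cell-type sharing annotation) and implements the downstream
    statistical characterisation of the variants captured by such a panel:
    quality filtering and frequency classification (common/rare/novel) of
    SNVs, enrichment of rare and novel variants across DHS cell-type-sharing
    levels, transcription-factor motif creation and disruption scanning with
    dynamic-programming p-values, and allele-specific-expression analyses
    (allelic-imbalance classification, vicinity and promoter-correlated
    enrichment, homozygous-eSNP stratification, residual variance explained).
    A synthetic-data module generates every pipeline input with planted
    ground truth so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
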