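#' GRCh37 (hg19) chromosome sizes
#'
#' Reference chromosome lengths in bp for the 22 autosomes, X, Y and the
#' mitochondrial genome. Used for genome-fraction arithmetic (e.g. what
#' share of the genome 300,000 100-bp bins represent) and as a realistic
#' sizes table for scaled examples.
#'
#' @return Named numeric vector of lengths in bp.
#' @export
grch37_chrom_sizes <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566,
    chrM = 16571)
}

#' Fraction of a genome covered by a set of fixed-width bins
#'
#' @param n_bins Number of bins.
#' @param bin_size Bin width in bp.
#' @param genome_bp Total genome length in bp (default: GRCh37 total).
#' @return Fraction in `[0, 1]`.
#' @examples
#' # 300,000 bins of 100 bp are about 1% of the human genome
#' genome_fraction(300000, 100)
#' @export
genome_fraction <- function(n_bins, bin_size = 100,
                            genome_bp = sum(grch37_chrom_sizes())) {
  (n_bins * bin_size) / genome_bp
}
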