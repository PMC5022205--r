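# Small shared fixtures, all built in code.

toy_grid <- function(sizes = c(chr1 = 1000, chr2 = 550), bin_size = 100) {
  bin_grid(sizes, bin_size)
}

default_pwm_library <- function() {
  list(informative_pwm("M1", "TGACGT"),
       informative_pwm("M2", "CCGGAA"),
       informative_pwm("M3", "CACGTG"),
       informative_pwm("M4", "ATTGCA"))
}

# CDS toy: one plus-strand and one minus-strand gene on a padded genome
toy_coding_world <- function() {
  plus_cds <- "ATGAAACCCGGGTTTACGTACGATTAA"   # 9 codons
  minus_cds <- "ATGCATGACTGGCATTGA"           # 6 codons (on the minus strand)
  seq <- paste0(strrep("A", 10), plus_cds, strrep("C", 10),
                revcomp_chr(minus_cds), strrep("G", 10))
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "chrZ"
  cds <- data.frame(
    tx_id = c("tplus", "tminus"),
    chrom = "chrZ",
    strand = c("+", "-"),
    start = c(10L, 10L + nchar(plus_cds) + 10L),
    end = c(10L + nchar(plus_cds),
            10L + nchar(plus_cds) + 10L + nchar(minus_cds)))
  list(genome = genome, cds = cds,
       plus_cds = plus_cds, minus_cds = minus_cds)
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

all_snvs_in <- function(genome, chrom, from, to) {
  seq <- as.character(genome[[chrom]])
  grid <- expand.grid(pos = from:to, alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  grid$chrom <- chrom
  grid$ref <- substring(seq, grid$pos, grid$pos)
  grid[grid$ref != grid$alt, c("chrom", "pos", "ref", "alt")]
}
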