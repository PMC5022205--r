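#' Fixed-width bin grid over a genome
#'
#' Partitions each chromosome into consecutive `bin_size`-bp bins using
#' 0-based half-open coordinates. The last bin of a chromosome may be short.
#' Bin ids are integers `1..n_bins(grid)`, ordered by chromosome (in the
#' order of `chrom_sizes`) and then by start coordinate, so that ordering by
#' bin id is the genomic order used for deterministic tie-breaking.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp (default 100, the panel-design grid).
#' @return An object of class `bin_grid`.
#' @examples
#' g <- bin_grid(c(chr1 = 1000, chr2 = 550), bin_size = 100)
#' n_bins(g)  # 10 + 6
#' @export
bin_grid <- function(chrom_sizes, bin_size = 100) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  if (bin_size < 1) stop("bin_size must be >= 1")
  sizes <- as.numeric(chrom_sizes)
  nb <- as.integer(ceiling(sizes / bin_size))
  offsets <- cumsum(c(0L, nb[-length(nb)]))
  names(offsets) <- names(chrom_sizes)
  structure(
    list(chrom_sizes = stats::setNames(sizes, names(chrom_sizes)),
         bin_size = as.integer(bin_size),
         bins_per_chrom = stats::setNames(nb, names(chrom_sizes)),
         offsets = offsets,
         n_bins = sum(nb)),
    class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("bin_grid:", length(x$chrom_sizes), "chromosomes,",
      x$n_bins, "bins of", x$bin_size, "bp\n")
  invisible(x)
}

#' Number of bins in a grid
#' @param grid A `bin_grid`.
#' @return Integer bin count.
#' @export
n_bins <- function(grid) grid$n_bins

#' Map bin ids to genomic intervals
#'
#' @param grid A `bin_grid`.
#' @param bin_ids Integer bin ids in `1..n_bins(grid)`.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
bin_to_interval <- function(grid, bin_ids) {
  if (any(bin_ids < 1 | bin_ids > grid$n_bins)) stop("bin id out of range")
  chrom_idx <- findInterval(bin_ids - 1L, grid$offsets)
  chrom <- names(grid$chrom_sizes)[chrom_idx]
  local <- bin_ids - 1L - grid$offsets[chrom_idx]
  start <- local * grid$bin_size
  end <- pmin(start + grid$bin_size, grid$chrom_sizes[chrom_idx])
  data.frame(chrom = chrom, start = start, end = unname(end),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Map genomic positions to bin ids
#'
#' @param grid A `bin_grid`.
#' @param chrom Chromosome names.
#' @param pos 0-based positions.
#' @return Integer bin ids; `NA` for positions outside the grid.
#' @export
pos_to_bin <- function(grid, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(pos, n)
  idx <- match(chrom, names(grid$chrom_sizes))
  ok <- !is.na(idx) & pos >= 0 & pos < grid$chrom_sizes[pmax(idx, 1L)]
  out <- rep(NA_integer_, length(pos))
  out[ok] <- grid$offsets[idx[ok]] + pos[ok] %/% grid$bin_size + 1L
  out
}

#' Bins as a GRanges object
#'
#' @param grid A `bin_grid`.
#' @param bin_ids Bin ids (default: all bins).
#' @return `GRanges` (1-based closed, as GRanges requires) with metadata
#'   column `bin_id`.
#' @export
bins_as_granges <- function(grid, bin_ids = seq_len(grid$n_bins)) {
  iv <- bin_to_interval(grid, bin_ids)
  gr <- GenomicRanges::GRanges(iv$chrom,
                               IRanges::IRanges(iv$start + 1L, iv$end))
  gr$bin_id <- bin_ids
  gr
}
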