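#' Normalize per-bin DNase-I coverage to a signal track
#'
#' Converts raw read counts on the bin grid to the dimensionless signal
#' used for ranking: reads in bin divided by total reads in the sample.
#' Input is either a numeric count vector over the full grid (one value per
#' bin) or a bedGraph-style `GRanges`/data.frame whose score mass is
#' apportioned to bins by bp overlap fraction, so reads spanning a bin
#' boundary are split proportionally and total mass is conserved.
#'
#' @param coverage Numeric vector of length `n_bins(grid)`, or a `GRanges`
#'   with a `score` column, or a data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), `score`.
#' @param grid A [bin_grid()].
#' @param sample_id,cell_type Optional identifiers carried on the track.
#' @return A `signal_track`: list with `values` (per-bin signal summing to
#'   1), `sample_id`, `cell_type`.
#' @export
bin_and_normalize <- function(coverage, grid, sample_id = NA_character_,
                              cell_type = NA_character_) {
  if (is.numeric(coverage) && is.null(dim(coverage))) {
    if (length(coverage) != grid$n_bins)
      stop("count vector length must equal n_bins(grid)")
    if (any(coverage < 0)) stop("negative counts")
    counts <- as.numeric(coverage)
  } else {
    df <- if (inherits(coverage, "GRanges")) {
      data.frame(chrom = as.character(GenomicRanges::seqnames(coverage)),
                 start = GenomicRanges::start(coverage) - 1L,
                 end = GenomicRanges::end(coverage),
                 score = coverage$score, stringsAsFactors = FALSE)
    } else as.data.frame(coverage)
    bad <- setdiff(unique(df$chrom), names(grid$chrom_sizes))
    if (length(bad))
      stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
    counts <- numeric(grid$n_bins)
    bs <- grid$bin_size
    for (i in seq_len(nrow(df))) {
      s <- df$start[i]; e <- df$end[i]
      if (e <= s) stop("malformed interval at record ", i)
      first <- pos_to_bin(grid, df$chrom[i], s)
      last <- pos_to_bin(grid, df$chrom[i], e - 1)
      ids <- first:last
      iv <- bin_to_interval(grid, ids)
      ov <- pmin(iv$end, e) - pmax(iv$start, s)
      counts[ids] <- counts[ids] + df$score[i] * ov / (e - s)
    }
  }
  tot <- sum(counts)
  if (tot == 0) stop("total signal is zero; cannot normalize")
  structure(list(values = counts / tot, sample_id = sample_id,
                 cell_type = cell_type),
            class = "signal_track")
}

track_values <- function(track) {
  if (inherits(track, "signal_track")) track$values else as.numeric(track)
}

#' Select the top-signal bins of one sample
#'
#' Ranks all bins by descending signal and returns the ids of the first
#' `n_top`. Ties are broken deterministically by genomic order (chromosome
#' order of the grid, then start coordinate), so zero-signal bins are
#' rankable and the cut always yields exactly `n_top` bins.
#'
#' @param track A `signal_track` or numeric vector over the grid.
#' @param n_top Number of bins to keep (the study design uses 300,000,
#'   about the top 1% of 100-bp bins of the human genome).
#' @param include_zero Rank zero-signal bins too (default TRUE, so
#'   `n_top` is always achieved); with FALSE the cut truncates at the
#'   last nonzero bin.
#' @return Integer vector of bin ids in rank order (class `ranked_bins`).
#' @export
select_top_bins <- function(track, n_top, include_zero = TRUE) {
  v <- track_values(track)
  if (n_top < 1) stop("n_top must be >= 1")
  if (n_top > length(v)) {
    warning("n_top exceeds number of bins; returning all bins")
    n_top <- length(v)
  }
  ord <- order(-v, seq_along(v))
  if (!include_zero) ord <- ord[v[ord] > 0]
  structure(ord[seq_len(min(n_top, length(ord)))], class = "ranked_bins")
}

#' Replicate-consensus bin set for one cell type
#'
#' With m >= 3 samples a bin is retained if present in at least half of
#' them (ceiling(m/2)); with exactly two samples it must be present in
#' both; a single sample's set is returned unchanged.
#'
#' @param ranked_sets List of bin-id vectors (one per sample of the same
#'   cell type); order within each vector is ignored.
#' @return Sorted integer vector of consensus bin ids.
#' @export
consensus_bins <- function(ranked_sets) {
  m <- length(ranked_sets)
  if (m == 0) stop("no ranked sets supplied")
  if (m == 1) return(sort(unique(as.integer(ranked_sets[[1]]))))
  need <- if (m == 2) 2L else as.integer(ceiling(m / 2))
  tab <- table(unlist(lapply(ranked_sets, function(s) unique(as.integer(s)))))
  sort(as.integer(names(tab)[tab >= need]))
}

#' Concordance filtering of rank blocks
#'
#' Groups each sample's ranked bins into consecutive blocks of
#' `block_size` ranks. A rank stratum is retained when the mean, over all
#' sample pairs, of the pairwise block overlap (|intersection| /
#' block_size, comparing blocks at the same rank range) is at least
#' `min_overlap`. Single-sample inputs retain every stratum (no pairs to
#' compare). Only complete blocks are considered.
#'
#' @param ranked_sets List of rank-ordered bin-id vectors.
#' @param block_size Ranks per block (study design: 50,000).
#' @param min_overlap Minimum mean pairwise overlap fraction (default 0.5).
#' @return List with `retained` (logical per stratum), `overlap` (mean
#'   pairwise overlap per stratum) and `sets` (per-sample bin vectors
#'   restricted to retained strata, rank order preserved).
#' @export
filter_rank_blocks <- function(ranked_sets, block_size = 50000,
                               min_overlap = 0.5) {
  if (!length(ranked_sets)) stop("no ranked sets supplied")
  lens <- lengths(ranked_sets)
  if (any(lens < block_size))
    stop("each ranked set must contain at least one full block")
  n_strata <- min(lens) %/% block_size
  m <- length(ranked_sets)
  overlap <- numeric(n_strata)
  for (j in seq_len(n_strata)) {
    idx <- ((j - 1) * block_size + 1):(j * block_size)
    blocks <- lapply(ranked_sets, function(s) s[idx])
    if (m == 1) { overlap[j] <- 1; next }
    pairs <- utils::combn(m, 2)
    ov <- apply(pairs, 2, function(p)
      length(intersect(blocks[[p[1]]], blocks[[p[2]]])) / block_size)
    overlap[j] <- mean(ov)
  }
  retained <- overlap >= min_overlap
  keep_idx <- unlist(lapply(which(retained), function(j)
    ((j - 1) * block_size + 1):(j * block_size)))
  sets <- lapply(ranked_sets, function(s) s[keep_idx])
  list(retained = retained, overlap = overlap, sets = sets)
}

as_bed_df <- function(x) {
  if (inherits(x, "GRanges")) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
               start = GenomicRanges::start(x) - 1L,
               end = GenomicRanges::end(x), stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(x)
    names(df)[1:3] <- c("chrom", "start", "end")
    df
  }
}

#' Remove bins dominated by exome capture regions
#'
#' A bin is removed when at least `min_frac` of its length overlaps the
#' union of the exome intervals (overlapping exome records are unioned
#' before measuring, so double-covered bp count once).
#'
#' @param bins Integer bin ids.
#' @param grid The [bin_grid()].
#' @param exome BED-like data.frame (`chrom`, `start`, `end`, 0-based
#'   half-open) or `GRanges` of exome capture targets.
#' @param min_frac Removal threshold as a fraction of bin length
#'   (default 0.5).
#' @return Bin ids surviving the subtraction, sorted.
#' @export
subtract_exome <- function(bins, grid, exome, min_frac = 0.5) {
  if (!length(bins)) return(integer(0))
  ex <- as_bed_df(exome)
  bad <- which(ex$end <= ex$start)
  if (length(bad))
    stop("malformed exome interval (end <= start) at line ", bad[1])
  ex_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end)))
  bin_gr <- bins_as_granges(grid, sort(unique(as.integer(bins))))
  hits <- GenomicRanges::findOverlaps(bin_gr, ex_gr)
  ovl <- numeric(length(bin_gr))
  if (length(hits)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      bin_gr[S4Vectors::queryHits(hits)], ex_gr[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    ovl[as.integer(names(agg))] <- agg
  }
  keep <- ovl < min_frac * GenomicRanges::width(bin_gr)
  bin_gr$bin_id[keep]
}

#' Assemble the capture panel from per-cell-type bin sets
#'
#' Takes the union of the (post-subtraction) consensus bin sets, merges
#' adjacent bins into maximal intervals, and annotates every bin with its
#' sharing level: the number of cell types whose set contains it.
#'
#' @param cell_type_bin_sets Named list (cell type -> bin-id vector).
#' @param grid The [bin_grid()].
#' @param extra_regions Optional named list of `GRanges`/BED data.frames
#'   (e.g. exome, HLA) appended as separate tracks without sharing levels.
#' @return A `capture_panel`: list with `bins` (data.frame `bin_id`,
#'   `sharing`), `intervals` (merged `GRanges`), `cell_types`,
#'   `total_target_bp`, `extra_regions`, and the `grid`.
#' @export
build_panel <- function(cell_type_bin_sets, grid, extra_regions = NULL) {
  if (!length(cell_type_bin_sets)) stop("need at least one cell type")
  sets <- lapply(cell_type_bin_sets, function(s) unique(as.integer(s)))
  tab <- table(unlist(sets))
  if (!length(tab)) stop("union of cell-type bin sets is empty")
  bins <- data.frame(bin_id = as.integer(names(tab)),
                     sharing = as.integer(tab))
  bins <- bins[order(bins$bin_id), , drop = FALSE]
  rownames(bins) <- NULL
  gr <- GenomicRanges::reduce(bins_as_granges(grid, bins$bin_id))
  structure(
    list(bins = bins,
         intervals = gr,
         cell_types = names(cell_type_bin_sets),
         total_target_bp = sum(GenomicRanges::width(gr)),
         extra_regions = extra_regions,
         grid = grid),
    class = "capture_panel")
}

#' @export
print.capture_panel <- function(x, ...) {
  cat("capture_panel:", nrow(x$bins), "bins in", length(x$intervals),
      "merged intervals,", x$total_target_bp, "bp;",
      length(x$cell_types), "cell types (max sharing",
      max(x$bins$sharing), ")\n")
  invisible(x)
}

#' Full panel design from per-sample signal tracks
#'
#' Runs the whole design for every cell type: rank bins per sample, keep
#' the top `n_top`, drop discordant rank blocks, take the replicate
#' consensus, subtract exome-dominated bins, then merge across cell types
#' with sharing-level annotation.
#'
#' @param tracks List of `signal_track`s (each carrying its `cell_type`).
#' @param n_top Top bins per sample.
#' @param block_size Ranks per concordance block; use `NULL` to skip block
#'   filtering (e.g. toy grids smaller than one block).
#' @param min_overlap Block-retention threshold.
#' @param exome Optional exome BED/`GRanges` to subtract.
#' @param min_frac Exome-overlap removal threshold per bin.
#' @param grid The [bin_grid()].
#' @param include_zero Passed to [select_top_bins()].
#' @return A `capture_panel`; attribute `"report"` holds a per-cell-type
#'   data.frame of sample and bin counts.
#' @export
design_panel <- function(tracks, grid, n_top, block_size = NULL,
                         min_overlap = 0.5, exome = NULL, min_frac = 0.5,
                         include_zero = TRUE) {
  ct <- vapply(tracks, function(t) t$cell_type, character(1))
  if (anyNA(ct)) stop("every track must carry a cell_type")
  sets <- list()
  report <- data.frame(cell_type = unique(ct), n_samples = NA_integer_,
                       n_bins = NA_integer_)
  for (i in seq_len(nrow(report))) {
    type <- report$cell_type[i]
    ranked <- lapply(tracks[ct == type], select_top_bins, n_top = n_top,
                     include_zero = include_zero)
    report$n_samples[i] <- length(ranked)
    if (!is.null(block_size) && length(ranked) > 1)
      ranked <- filter_rank_blocks(ranked, block_size, min_overlap)$sets
    cons <- consensus_bins(ranked)
    if (!is.null(exome)) cons <- subtract_exome(cons, grid, exome, min_frac)
    report$n_bins[i] <- length(cons)
    sets[[type]] <- cons
  }
  panel <- build_panel(sets, grid)
  attr(panel, "report") <- report
  panel
}
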