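#' Write per-bin counts as bedGraph
#'
#' Zero-count bins are omitted, as is conventional for sparse coverage
#' tracks.
#'
#' @param counts Numeric vector over the grid.
#' @param grid The [bin_grid()].
#' @param path Output file.
#' @export
write_bedgraph <- function(counts, grid, path) {
  nz <- which(counts > 0)
  iv <- bin_to_interval(grid, nz)
  df <- data.frame(iv$chrom, as.integer(iv$start), as.integer(iv$end),
                   counts[nz])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a per-bin count vector
#'
#' Uses `rtracklayer` when available, otherwise plain table parsing of
#' the 4-column format; mass is apportioned to bins by overlap via
#' [bin_and_normalize()] conventions.
#'
#' @param path bedGraph file.
#' @param grid The [bin_grid()].
#' @return data.frame `chrom`, `start`, `end`, `score` suitable for
#'   [bin_and_normalize()].
#' @export
read_bedgraph <- function(path, grid) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr), score = gr$score,
               stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    names(df) <- c("chrom", "start", "end", "score")
    df
  }
}

#' Write chromosome sizes TSV
#' @param chrom_sizes Named vector.
#' @param path Output file.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  utils::write.table(data.frame(names(chrom_sizes), as.integer(chrom_sizes)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write panel intervals as BED with a sharing-level column
#'
#' Emits one record per maximal run of consecutive bins with a constant
#' sharing level (BED3 + sharing as the 4th column, 0-based half-open).
#'
#' @param panel A `capture_panel`.
#' @param path Output file.
#' @export
write_panel_bed <- function(panel, path) {
  iv <- bin_to_interval(panel$grid, panel$bins$bin_id)
  iv$sharing <- panel$bins$sharing
  run_break <- c(TRUE, diff(panel$bins$bin_id) != 1 |
                   diff(panel$bins$sharing) != 0 |
                   iv$chrom[-1] != iv$chrom[-nrow(iv)])
  run <- cumsum(run_break)
  merged <- do.call(rbind, lapply(split(iv, run), function(d)
    data.frame(chrom = d$chrom[1], start = as.integer(min(d$start)),
               end = as.integer(max(d$end)), sharing = d$sharing[1])))
  merged <- merged[order(match(merged$chrom, names(panel$grid$chrom_sizes)),
                         merged$start), ]
  utils::write.table(merged, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a minimal VCF v4.2 for simulated SNVs
#'
#' Site INFO carries MQ; per-sample FORMAT is GT:DP:GQ:AD (AD as
#' "ref,alt" read counts, from which the reference-allele balance is
#' recovered).
#'
#' @param variants,genotypes Tables as produced by [simulate_variants()].
#' @param path Output file.
#' @export
write_vcf <- function(variants, genotypes, path) {
  samples <- sort(unique(genotypes$sample))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  g <- genotypes
  g$field <- paste0(g$gt, ":", g$dp, ":", g$gq, ":", g$ad_ref, ",",
                    g$dp - g$ad_ref)
  wide <- matrix("./.", nrow = nrow(variants), ncol = length(samples),
                 dimnames = list(variants$variant_id, samples))
  wide[cbind(match(g$variant_id, variants$variant_id),
             match(g$sample, samples))] <- g$field
  lines <- paste(variants$chrom, variants$pos, variants$variant_id,
                 variants$ref, variants$alt, ".", "PASS",
                 paste0("MQ=", variants$mq), "GT:DP:GQ:AD",
                 apply(wide, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into the package's variant/genotype tables
#'
#' Parsing goes through `vcfR`; DP, GQ and AD are extracted per call and
#' the site MQ from INFO.
#'
#' @param path VCF file (plain or gzipped).
#' @return List with `variants` and `genotypes` data.frames.
#' @export
read_variant_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  variants <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, mq = mq, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, "GT")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, "GQ", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  ad_ref <- suppressWarnings(
    apply(ad, 2, function(x) as.integer(sub(",.*", "", x))))
  genotypes <- data.frame(
    variant_id = rep(variants$variant_id, ncol(gt)),
    sample = rep(colnames(gt), each = nrow(gt)),
    gt = as.vector(gt), dp = as.vector(dp), gq = as.vector(gq),
    ad_ref = as.vector(ad_ref), stringsAsFactors = FALSE)
  genotypes <- genotypes[!is.na(genotypes$gt) & genotypes$gt != "./.", ]
  list(variants = variants, genotypes = genotypes)
}

#' Write PWMs in MEME-like probability-matrix text
#'
#' @param pwms List of [new_pwm()] objects.
#' @param path Output file.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA, pwms[[1]]$background),
                     collapse = " "), ""), con)
  for (p in pwms) {
    writeLines(c(paste("MOTIF", p$id),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         p$width)), con)
    writeLines(apply(p$probs_raw, 2, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from MEME-like probability-matrix text
#'
#' @param path MEME-format file (probability matrices; ACGT alphabet).
#' @param background Background distribution for scoring (default: the
#'   file's background line, else uniform).
#' @return List of [new_pwm()] objects.
#' @export
read_meme <- function(path, background = NULL) {
  lines <- readLines(path)
  if (is.null(background)) {
    bi <- grep("^Background letter frequencies", lines)
    if (length(bi)) {
      tok <- strsplit(trimws(lines[bi[1] + 1]), "\\s+")[[1]]
      background <- as.numeric(tok[seq(2, 8, by = 2)])
    } else background <- rep(0.25, 4)
  }
  motif_at <- grep("^MOTIF", lines)
  lapply(motif_at, function(i) {
    id <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
    hdr <- grep("letter-probability matrix", lines[i:length(lines)])[1] + i - 1
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    probs <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    new_pwm(id, t(probs), background = background)
  })
}

#' Serialize planted ground truth to JSON
#'
#' @param truth A `synthetic_truth` object.
#' @param path Output file.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  # named atomic vectors serialize as JSON objects so names survive
  for (nm in names(x))
    if (is.atomic(x[[nm]]) && !is.null(names(x[[nm]])))
      x[[nm]] <- as.list(x[[nm]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Load planted ground truth from JSON
#'
#' @param path JSON file from [write_truth()].
#' @return A `synthetic_truth` list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in intersect(names(x), c("classes", "levels", "sign")))
    x[[nm]] <- unlist(x[[nm]])
  structure(x, class = "synthetic_truth")
}
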