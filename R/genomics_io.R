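#' Convert BED intervals to bin indices
#'
#' Reads a BED file (0-based, half-open intervals) and maps interval
#' positions onto fixed-size bins, returning sorted unique 1-based bin
#' indices. Useful for turning reference TAD boundaries or CTCF binding
#' sites into the bin coordinates of a contact map. Parsing goes through
#' \pkg{rtracklayer} when available and falls back to a plain three-column
#' reader otherwise.
#'
#' @param path BED file path.
#' @param bin_size bin width in bp.
#' @param chrom optional chromosome name filter (e.g. `"chr1"`).
#' @param use `"start"` maps each interval's start position to a bin
#'   (appropriate for boundary/point annotations); `"midpoint"` uses the
#'   interval midpoint.
#' @return sorted unique integer bin indices (1-based).
#' @export
read_bed_bins <- function(path, bin_size, chrom = NULL,
                          use = c("start", "midpoint")) {
  use <- match.arg(use)
  df <- read_bed3(path)
  if (!is.null(chrom)) df <- df[df$chrom == chrom, , drop = FALSE]
  if (!nrow(df)) return(integer())
  pos <- if (use == "start") df$start else (df$start + df$end) / 2
  sort(unique(as.integer(pos %/% bin_size) + 1L))
}

read_bed3 <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,  # back to 0-based
               end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
  } else {
    df <- read.table(path, sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
    data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
               end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  }
}

#' Average a bedGraph signal over fixed-size bins
#'
#' Reads a bedGraph track (0-based, half-open intervals with a value
#' column) and computes the coverage-weighted mean value per bin, for use
#' with [signal_by_community()].
#'
#' @param path bedGraph file path.
#' @param bin_size bin width in bp.
#' @param n_bins number of bins of the companion contact map.
#' @param chrom optional chromosome name filter.
#' @return numeric vector of length `n_bins` (`NA` where the track has no
#'   coverage).
#' @export
read_bedgraph_track <- function(path, bin_size, n_bins, chrom = NULL) {
  df <- if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               value = as.numeric(gr$score), stringsAsFactors = FALSE)
  } else {
    raw <- read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(raw) < 4) stop("bedGraph file needs 4 columns: ", path)
    data.frame(chrom = as.character(raw[[1]]), start = as.integer(raw[[2]]),
               end = as.integer(raw[[3]]), value = as.numeric(raw[[4]]),
               stringsAsFactors = FALSE)
  }
  if (!is.null(chrom)) df <- df[df$chrom == chrom, , drop = FALSE]
  wsum <- numeric(n_bins)
  wlen <- numeric(n_bins)
  for (r in seq_len(nrow(df))) {
    a <- df$start[r]
    b <- df$end[r]
    first <- as.integer(a %/% bin_size)
    last <- as.integer((b - 1L) %/% bin_size)
    for (bin in first:last) {
      if (bin >= n_bins) break
      lo <- max(a, bin * bin_size)
      hi <- min(b, (bin + 1) * bin_size)
      if (hi > lo) {
        wsum[bin + 1L] <- wsum[bin + 1L] + df$value[r] * (hi - lo)
        wlen[bin + 1L] <- wlen[bin + 1L] + (hi - lo)
      }
    }
  }
  out <- ifelse(wlen > 0, wsum / wlen, NA_real_)
  out
}
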