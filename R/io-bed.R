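#' Read ChIP-seq peak calls from a BED file
#'
#' Accepts BED3+ with 0-based half-open intervals. The returned peak set
#' answers point-containment queries for 1-based SNP positions: a SNP at
#' `pos` is inside `(start, end)` iff `start <= pos - 1 < end`.
#'
#' @param path BED file path (3+ tab-separated columns, no header), or a
#'   data.frame with columns chrom, start, end.
#' @param tf transcription factor label.
#' @param cell_line cell line label.
#' @return an object of class `peak_set`.
#' @export
read_bed_peaks <- function(path, tf = NA_character_, cell_line = NA_character_) {
  if (is.character(path)) {
    if (file.size(path) == 0L) {
      df <- data.frame(chrom = character(), start = integer(), end = integer())
    } else {
      df <- data.table::fread(path, sep = "\t", header = FALSE)
      data.table::setnames(df, seq_len(min(3L, ncol(df))),
                           c("chrom", "start", "end")[seq_len(min(3L, ncol(df)))])
    }
  } else df <- path
  if (nrow(df) > 0) {
    bad <- which(df$start >= df$end)
    if (length(bad))
      stop_fmt("asb_format_error", "BED interval with start >= end at line %d",
               bad[1])
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = as.integer(df$start) + 1L,
                              end = as.integer(df$end)))
  structure(list(gr = gr, tf = tf, cell_line = cell_line), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d intervals, tf=%s, cell_line=%s\n",
              length(x$gr), x$tf, x$cell_line))
  invisible(x)
}

#' Test whether SNP positions fall inside peaks
#'
#' @param peaks a `peak_set` from [read_bed_peaks()].
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions (recycled against
#'   `chrom`).
#' @return logical vector; positions on chromosomes absent from the peak
#'   set are `FALSE` (not an error).
#' @export
peaks_contain <- function(peaks, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  if (length(peaks$gr) == 0L) return(rep(FALSE, n))
  lvls <- union(GenomeInfoDb::seqlevels(peaks$gr), unique(chrom))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos),
                              seqlengths = setNames(rep(NA_integer_, length(lvls)), lvls))
  subj <- peaks$gr
  GenomeInfoDb::seqlevels(subj) <- lvls
  GenomicRanges::countOverlaps(q, subj) > 0L
}
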