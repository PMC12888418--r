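#' Construct a motif object
#'
#' A motif is a position probability matrix over A, C, G, T together with its
#' provenance: `source` records whether it came from the JASPAR reference set
#' or from de novo k-mer discovery, and `motif_class` records how a
#' discovered motif relates to the reference set (`canonical` for the
#' ChIPped TF's own JASPAR motif, `redundant`/`accessory`/`de_novo` for
#' discovered motifs, `unclassified` before classification).
#'
#' @param name motif identifier.
#' @param matrix numeric matrix, one row per position, columns A, C, G, T;
#'   every row must sum to 1 (tolerance 1e-9) and be nonnegative. At least 4
#'   positions.
#' @param source `"JASPAR"` or `"NoPeak"`.
#' @param tf associated transcription factor label, or `NA`.
#' @param kmer_support number of k-mers supporting a discovered motif
#'   (`NA` for reference motifs).
#' @param motif_class one of `canonical`, `redundant`, `accessory`,
#'   `de_novo`, `unclassified`.
#' @return an object of class `motif`.
#' @export
motif <- function(name, matrix, source = c("JASPAR", "NoPeak"), tf = NA_character_,
                  kmer_support = NA_integer_,
                  motif_class = c("unclassified", "canonical", "redundant",
                                  "accessory", "de_novo")) {
  source <- match.arg(source)
  motif_class <- match.arg(motif_class)
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4L)
    stop_fmt("asb_format_error", "motif '%s': matrix must have 4 columns (A,C,G,T)", name)
  if (nrow(matrix) < 4L)
    stop_fmt("asb_format_error", "motif '%s': length %d < 4", name, nrow(matrix))
  if (any(matrix < 0))
    stop_fmt("asb_format_error", "motif '%s': negative probabilities", name)
  if (any(abs(rowSums(matrix) - 1) > 1e-9))
    stop_fmt("asb_format_error", "motif '%s': rows must sum to 1", name)
  colnames(matrix) <- .BASES
  structure(list(name = name, matrix = matrix, source = source, tf = tf,
                 kmer_support = kmer_support, motif_class = motif_class),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif %s> source=%s tf=%s class=%s length=%d\n",
              x$name, x$source, x$tf, x$motif_class, nrow(x$matrix)))
  cat("consensus:", motif_consensus(x), "\n")
  invisible(x)
}

motif_length <- function(m) nrow(m$matrix)

#' Reverse complement of a motif
#'
#' @param m a [motif()].
#' @return the reverse-complemented motif (positions reversed, A/T and C/G
#'   columns swapped), name suffixed `_rc`.
#' @export
revcomp_motif <- function(m) {
  mat <- m$matrix[rev(seq_len(nrow(m$matrix))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(mat) <- .BASES
  out <- m
  out$matrix <- mat
  out$name <- paste0(m$name, "_rc")
  out
}

#' Per-position information content of a motif
#'
#' IC of a column with probabilities p is `2 + sum(p * log2(p))` bits
#' (0 for a uniform column, 2 for a one-hot column).
#'
#' @param m a [motif()].
#' @return numeric vector of IC values, one per position.
#' @export
motif_ic <- function(m) {
  apply(m$matrix, 1L, function(p) {
    lp <- ifelse(p > 0, log2(p), 0)
    2 + sum(p * lp)
  })
}

motif_consensus <- function(m) paste(.BASES[max.col(m$matrix, "first")], collapse = "")

# log2 odds matrix against a background distribution
motif_logodds <- function(m, background) {
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6)
    stop_fmt("asb_config_error", "background must be 4 probabilities summing to 1")
  sweep(log2(m$matrix), 2L, log2(background), `-`)
}
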