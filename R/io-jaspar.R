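#' Read motifs from JASPAR PFM text
#'
#' Parses the JASPAR position frequency matrix text format: each record is a
#' `>`-header (`>NAME TF`) followed by four count rows for A, C, G and T
#' (with or without the base letter and square brackets). Counts are
#' converted to per-position probabilities column-wise after adding a
#' pseudocount to every count, which avoids minus-infinity log-odds for
#' zero-count cells.
#'
#' @param path path to a PFM text file, or a character vector of lines.
#' @param pseudocount value added to each count before normalisation
#'   (default 0.01).
#' @return list of [motif()] objects (source `"JASPAR"`), in file order.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 0.01) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) return(list())
  ends <- c(hdr[-1] - 1L, length(lines))
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    h <- sub("^>\\s*", "", lines[hdr[i]])
    toks <- strsplit(trimws(h), "\\s+")[[1]]
    name <- toks[1]
    tf <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else NA_character_
    body <- lines[seq(hdr[i] + 1L, ends[i])]
    if (length(body) != 4L)
      stop_fmt("asb_format_error",
               "record '%s': expected 4 base rows, found %d", name, length(body))
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ \t]*[ACGTacgt][ \t]*", "", ln)
      ln <- gsub("[][]", " ", ln)
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals))
        stop_fmt("asb_format_error", "record '%s': non-numeric entry", name)
      vals
    })
    len <- unique(lengths(rows))
    if (length(len) != 1L)
      stop_fmt("asb_format_error", "record '%s': ragged count rows", name)
    if (len == 0L)
      stop_fmt("asb_format_error", "record '%s': zero-length matrix", name)
    counts <- do.call(cbind, rows) + pseudocount      # positions x bases
    probs <- counts / rowSums(counts)
    out[[i]] <- motif(name, probs, source = "JASPAR", tf = tf)
  }
  out
}

#' Write motifs as JASPAR PFM text
#'
#' Probabilities are scaled back to pseudo-counts using `kmer_support` when
#' available (default scale 100), which round-trips through
#' [read_jaspar_pfm()] up to the pseudocount.
#'
#' @param motifs list of [motif()] objects.
#' @param path output file.
#' @param digits decimal digits for counts.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(motifs, path, digits = 4) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    scale <- if (!is.na(m$kmer_support)) m$kmer_support else 100
    counts <- t(m$matrix) * scale                      # bases x positions
    writeLines(sprintf(">%s %s", m$name, ifelse(is.na(m$tf), "", m$tf)), con)
    for (b in seq_len(4L)) {
      writeLines(sprintf("%s  [ %s ]", .BASES[b],
                         paste(formatC(counts[b, ], digits = digits, format = "fg"),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}
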