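# sum of log-odds lookups at every placement; codes may contain NA (N bases),
# which force the placement score to -Inf so it never wins a maximum.
scan_codes <- function(lmat, codes) {
  L <- nrow(lmat)
  n <- length(codes) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    v <- lmat[j, codes[j:(j + n - 1L)]]
    v[is.na(v)] <- -Inf
    s <- s + v
  }
  s
}

#' Scan a sequence with a motif's log-odds matrix
#'
#' The score at placement `i` on a strand is
#' `sum_j log2(P_motif[j, base_j] / P_bg[base_j])` over the motif columns.
#' The reverse-strand score at placement `i` is the forward score of the
#' reverse-complemented motif at the same placement, i.e. the motif read off
#' the opposite strand of the same window.
#'
#' @param m a [motif()].
#' @param sequence character scalar (ACGT, N allowed) or integer codes.
#' @param background base probabilities for A,C,G,T (default uniform);
#'   a zero background probability for a base present in the sequence is an
#'   error.
#' @return numeric matrix with rows `"+"` and `"-"`, one column per
#'   placement; positions containing N score `-Inf`.
#' @export
logodds_scan <- function(m, sequence, background = rep(0.25, 4)) {
  codes <- if (is.numeric(sequence)) sequence else encode_seq(sequence)
  present <- sort(unique(codes[!is.na(codes)]))
  if (any(background[present] == 0))
    stop_fmt("asb_config_error",
             "background has zero probability for a base present in the sequence")
  lf <- motif_logodds(m, background)
  lr <- motif_logodds(revcomp_motif(m), background)
  fwd <- scan_codes(lf, codes)
  rev_ <- scan_codes(lr, codes)
  out <- rbind(fwd, rev_)
  rownames(out) <- c("+", "-")
  out
}

# best score over both strands restricted to given placements
best_scan_score <- function(scores, placements = seq_len(ncol(scores))) {
  if (length(placements) == 0L || ncol(scores) == 0L) return(-Inf)
  max(scores[, placements, drop = FALSE])
}

#' Match-score threshold calibrated to a false positive rate
#'
#' Finds the threshold `t` such that a random background window of
#' `window_len` bases has best scan score (both strands, all placements)
#' reaching `t` with probability about `fpr`: `t` is the empirical
#' `1 - fpr` quantile (inverse-ECDF) of the best-score distribution.
#' `method = "exact"` enumerates all `4^window_len` windows (weighted by
#' background probability); `"mc"` uses seeded Monte-Carlo draws.
#'
#' @param m a [motif()].
#' @param background base probabilities (default uniform).
#' @param fpr target false positive rate in (0,1); the published mapping
#'   uses 5e-2.
#' @param window_len background window length (default 51, matching the
#'   +/- 25 bp SNP windows).
#' @param method `"auto"` (exact when `window_len <= 12` and motif length
#'   `<= 8`, else Monte-Carlo), `"exact"` or `"mc"`.
#' @param n_draws Monte-Carlo sample size.
#' @param seed RNG seed for Monte-Carlo mode.
#' @return scalar threshold.
#' @export
fpr_threshold <- function(m, background = rep(0.25, 4), fpr = 0.05,
                          window_len = 51L, method = c("auto", "exact", "mc"),
                          n_draws = 100000L, seed = 1L) {
  if (fpr <= 0 || fpr >= 1) stop_fmt("asb_config_error", "fpr must be in (0,1)")
  method <- match.arg(method)
  L <- motif_length(m)
  if (window_len < L)
    stop_fmt("asb_config_error", "window_len %d shorter than motif (%d)", window_len, L)
  if (method == "auto")
    method <- if (window_len <= 12L && L <= 8L) "exact" else "mc"
  lf <- motif_logodds(m, background)
  lr <- motif_logodds(revcomp_motif(m), background)
  n_place <- window_len - L + 1L

  best_of_chunk <- function(codes_mat) {
    # codes_mat: windows x window_len integer matrix of base codes
    best <- rep(-Inf, nrow(codes_mat))
    for (p in seq_len(n_place)) {
      for (lmat in list(lf, lr)) {
        sc <- rep(0, nrow(codes_mat))
        for (j in seq_len(L)) sc <- sc + lmat[j, codes_mat[, p + j - 1L]]
        best <- pmax(best, sc)
      }
    }
    best
  }

  if (method == "exact") {
    n_win <- 4^window_len
    chunk <- 262144L
    acc <- NULL
    idx0 <- 0
    lbg <- log(background)
    while (idx0 < n_win) {
      sz <- as.integer(min(chunk, n_win - idx0))
      idx <- idx0 + seq_len(sz) - 1
      codes_mat <- matrix(0L, sz, window_len)
      rem <- idx
      for (j in seq_len(window_len)) {    # base-4 digits, most significant first
        d <- rem %/% 4^(window_len - j)
        rem <- rem - d * 4^(window_len - j)
        codes_mat[, j] <- as.integer(d) + 1L
      }
      lw <- rowSums(matrix(lbg[codes_mat], sz, window_len))
      best <- best_of_chunk(codes_mat)
      part <- data.table::data.table(score = round(best, 9), w = exp(lw))
      acc <- data.table::rbindlist(list(acc, part[, .(w = sum(w)), by = score]))
      idx0 <- idx0 + sz
    }
    dist <- acc[, .(w = sum(w)), by = score]
    data.table::setorder(dist, score)
    cw <- cumsum(dist$w) / sum(dist$w)
    dist$score[which(cw >= 1 - fpr)[1]]
  } else {
    best <- with_seed(seed, {
      codes_mat <- matrix(sample.int(4L, n_draws * window_len, replace = TRUE,
                                     prob = background),
                          n_draws, window_len)
      best_of_chunk(codes_mat)
    })
    s <- sort(best)
    s[max(1L, ceiling((1 - fpr) * n_draws))]
  }
}

#' Score a heterozygous SNP against one motif
#'
#' Extracts the +/- `flank` bp window around the SNP from the reference
#' sequence, forces the central base to the REF allele (REF window) and to
#' the ALT allele (ALT window), and scores each window with the motif over
#' both strands, restricted to placements that overlap the central
#' position - so the score reflects the variant, not a distal match.
#' The motif score difference MSD is `ref_score - alt_score`, and the SNP
#' "matches" the motif when either allele's best score reaches the FPR
#' threshold.
#'
#' @param m a [motif()].
#' @param genome named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param snp one-row data.frame (or list) with `snp_id`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param peaks a `peak_set` (or NULL, then `in_peak = FALSE`).
#' @param flank half-window (default 25, i.e. 51-mer windows).
#' @param threshold match threshold from [fpr_threshold()].
#' @param background base probabilities.
#' @return one-row `data.table`: `snp_id`, `motif`, `ref_score`,
#'   `alt_score`, `msd`, `matches`, `in_peak`.
#' @export
score_het_snp <- function(m, genome, snp, peaks = NULL, flank = 25L,
                          threshold = -Inf, background = rep(0.25, 4)) {
  chrom_seq <- if (inherits(genome, "DNAStringSet"))
    as.character(genome[[as.character(snp$chrom)]]) else genome[[as.character(snp$chrom)]]
  clen <- nchar(chrom_seq)
  pos <- as.integer(snp$pos)
  w_start <- max(1L, pos - flank)
  w_end <- min(clen, pos + flank)
  if (w_end - w_start + 1L < 2L * flank + 1L)
    message(sprintf("SNP %s: window truncated at chromosome edge", snp$snp_id))
  codes <- encode_seq(substr(chrom_seq, w_start, w_end))
  center <- pos - w_start + 1L
  ref_code <- match(toupper(snp$ref), .BASES)
  alt_code <- match(toupper(snp$alt), .BASES)
  gbase <- codes[center]
  if (!is.na(gbase) && gbase != ref_code && gbase != alt_code)
    warning(sprintf("SNP %s: reference base %s matches neither REF nor ALT",
                    snp$snp_id, .BASES[gbase]))
  L <- motif_length(m)
  nwin <- length(codes)
  placements <- seq.int(max(1L, center - L + 1L), min(nwin - L + 1L, center))
  if (length(placements) == 0L || placements[1] > placements[length(placements)]) {
    ref_score <- alt_score <- -Inf
  } else {
    ref_codes <- codes; ref_codes[center] <- ref_code
    alt_codes <- codes; alt_codes[center] <- alt_code
    ref_score <- best_scan_score(logodds_scan(m, ref_codes, background), placements)
    alt_score <- best_scan_score(logodds_scan(m, alt_codes, background), placements)
  }
  in_peak <- if (is.null(peaks)) FALSE else peaks_contain(peaks, snp$chrom, pos)
  data.table::data.table(
    snp_id = as.character(snp$snp_id), motif = m$name,
    ref_score = ref_score, alt_score = alt_score, msd = ref_score - alt_score,
    matches = max(ref_score, alt_score) >= threshold, in_peak = in_peak)
}

#' Trim low-information edges off a motif
#'
#' Strips columns from each end while the column information content
#' (`2 + sum(p log2 p)` bits) is below `min_ic`, never trimming below 4
#' columns.
#'
#' @param m a [motif()].
#' @param min_ic IC threshold in bits (default 0.25).
#' @return the trimmed motif.
#' @export
trim_motif_edges <- function(m, min_ic = 0.25) {
  ic <- motif_ic(m)
  lo <- 1L
  hi <- length(ic)
  while (hi - lo + 1L > 4L && ic[lo] < min_ic) lo <- lo + 1L
  while (hi - lo + 1L > 4L && ic[hi] < min_ic) hi <- hi - 1L
  if (lo == 1L && hi == length(ic)) return(m)
  out <- m
  out$matrix <- m$matrix[lo:hi, , drop = FALSE]
  out
}
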