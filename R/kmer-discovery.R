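canonical_kmer <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Build k-mer read-start score profiles
#'
#' For every genomic occurrence of every canonical k-mer (the
#' lexicographic minimum of a k-mer and its reverse complement), counts
#' read 5' starts at each offset in `-W..W` from the occurrence start.
#' Reverse-strand reads contribute their 5' end (the interval end in BED
#' coordinates) with a sign-flipped offset. K-mers whose read-start
#' profile is enriched directly over their occurrences are the raw signal
#' of TF binding footprints, without any peak calls.
#'
#' @param read_intervals data.frame of reads with columns `chrom`,
#'   `start`, `end` (0-based half-open, BED-style) and `strand`
#'   (`"+"`/`"-"`).
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param k k-mer length in `[4, 12]` (default 8).
#' @param window_W half-width of the offset window (default 200).
#' @param min_occurrences only materialise profiles for k-mers with at
#'   least this many genomic occurrences (memory guard; selection applies
#'   its own, higher, occurrence filter).
#' @return a `kmer_profile_set`: aggregated offset counts plus occurrence
#'   counts; individual dense profiles are available via
#'   [kmer_profile()] / `as.list()`.
#' @export
build_kmer_profiles <- function(read_intervals, genome, k = 8L, window_W = 200L,
                                min_occurrences = 2L) {
  if (k < 4L || k > 12L)
    stop_fmt("asb_config_error", "k = %d outside [4, 12]", k)
  empty <- structure(list(counts = data.table::data.table(
    kmer = character(), offset = integer(), n = integer()),
    occ = data.table::data.table(kmer = character(), n_occurrences = integer()),
    k = k, W = as.integer(window_W)), class = "kmer_profile_set")
  if (is.null(read_intervals) || nrow(read_intervals) == 0L) return(empty)
  reads <- data.table::as.data.table(read_intervals)
  reads[, five_prime := ifelse(strand == "-", as.integer(end),
                               as.integer(start) + 1L)]   # 1-based 5' position
  chroms <- if (inherits(genome, "DNAStringSet"))
    setNames(as.character(genome), names(genome)) else genome
  occ_list <- list()
  cnt_list <- list()
  for (ch in intersect(names(chroms), unique(reads$chrom))) {
    seq_ch <- toupper(chroms[[ch]])
    L <- nchar(seq_ch)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    km <- substring(seq_ch, starts, starts + k - 1L)
    ok <- !grepl("[^ACGT]", km)
    occ <- data.table::data.table(kmer = canonical_kmer(km[ok]), pos = starts[ok])
    n_occ <- occ[, .(n_occurrences = .N), by = kmer]
    keep <- n_occ[n_occurrences >= min_occurrences, kmer]
    occ <- occ[kmer %in% keep]
    occ_list[[ch]] <- n_occ
    if (nrow(occ) == 0L) next
    r5 <- reads[chrom == ch]
    if (nrow(r5) == 0L) next
    data.table::setorder(r5, five_prime)
    fp <- r5$five_prime
    sgn <- ifelse(r5$strand == "-", -1L, 1L)
    lo <- findInterval(occ$pos - window_W - 1L, fp) + 1L
    hi <- findInterval(occ$pos + window_W, fp)
    lens <- pmax(0L, hi - lo + 1L)
    if (sum(lens) == 0L) next
    occ_idx <- rep.int(seq_len(nrow(occ)), lens)
    read_idx <- sequence(lens) + rep.int(lo - 1L, lens)
    inc <- data.table::data.table(
      kmer = occ$kmer[occ_idx],
      offset = as.integer(sgn[read_idx] * (fp[read_idx] - occ$pos[occ_idx])))
    inc <- inc[abs(offset) <= window_W]
    cnt_list[[ch]] <- inc[, .(n = .N), by = .(kmer, offset)]
  }
  if (length(occ_list) == 0L) return(empty)
  occ_all <- data.table::rbindlist(occ_list)[, .(n_occurrences = sum(n_occurrences)),
                                             by = kmer]
  cnt_all <- if (length(cnt_list))
    data.table::rbindlist(cnt_list)[, .(n = sum(n)), by = .(kmer, offset)]
  else data.table::data.table(kmer = character(), offset = integer(), n = integer())
  structure(list(counts = cnt_all, occ = occ_all, k = k, W = as.integer(window_W)),
            class = "kmer_profile_set")
}

#' @export
print.kmer_profile_set <- function(x, ...) {
  cat(sprintf("<kmer_profile_set> k=%d W=%d, %d k-mers with profiles\n",
              x$k, x$W, length(unique(x$counts$kmer))))
  invisible(x)
}

#' Dense profile for one k-mer
#'
#' @param profiles a `kmer_profile_set`.
#' @param kmer canonical k-mer string.
#' @return list with `kmer`, `profile` (integer histogram over offsets
#'   `-W..W`, length `2W+1`) and `n_occurrences`.
#' @export
kmer_profile <- function(profiles, kmer) {
  W <- profiles$W
  prof <- integer(2L * W + 1L)
  keep_cnt <- which(profiles$counts$kmer == kmer)   # avoid column shadowing
  sub <- profiles$counts[keep_cnt]
  prof[sub$offset + W + 1L] <- sub$n
  nocc <- profiles$occ$n_occurrences[profiles$occ$kmer == kmer]
  list(kmer = kmer, profile = prof,
       n_occurrences = if (length(nocc)) nocc else 0L)
}

#' Select k-mers whose profiles indicate TF binding
#'
#' A binding-consistent profile has an increased read-start frequency over
#' the k-mer itself: the smoothed central read density (offsets
#' `|d| <= fragment_half`) must exceed `enrichment_min` times the flank
#' density (`fragment_half < |d| <= W`), and the k-mer must occur at least
#' `min_occurrences` times.
#'
#' @param profiles a `kmer_profile_set` from [build_kmer_profiles()].
#' @param enrichment_min minimum central/flank density ratio (default 2).
#' @param min_occurrences minimum genomic occurrences (default 50).
#' @param fragment_half central half-width in bp (default 100).
#' @return `data.table` with `kmer`, `n_occurrences`, `central_density`,
#'   `flank_density`, `enrichment`, ordered by decreasing enrichment.
#' @export
select_binding_kmers <- function(profiles, enrichment_min = 2.0,
                                 min_occurrences = 50L, fragment_half = 100L) {
  W <- profiles$W
  if (fragment_half >= W)
    stop_fmt("asb_config_error", "fragment_half must be < window_W")
  cnt <- profiles$counts
  eligible <- profiles$occ[n_occurrences >= min_occurrences]
  if (nrow(eligible) == 0L || nrow(cnt) == 0L)
    return(data.table::data.table(kmer = character(), n_occurrences = integer(),
                                  central_density = numeric(), flank_density = numeric(),
                                  enrichment = numeric()))
  cnt <- cnt[kmer %in% eligible$kmer]
  agg <- cnt[, .(central = sum(n[abs(offset) <= fragment_half]),
                 flank = sum(n[abs(offset) > fragment_half])), by = kmer]
  agg <- merge(agg, eligible, by = "kmer")
  n_central <- 2L * fragment_half + 1L
  n_flank <- 2L * (W - fragment_half)
  agg[, central_density := (central + 1) / n_central]
  agg[, flank_density := (flank + 1) / n_flank]
  agg[, enrichment := central_density / flank_density]
  out <- agg[enrichment > enrichment_min,
             .(kmer, n_occurrences, central_density, flank_density, enrichment)]
  data.table::setorder(out, -enrichment, kmer)[]
}

# ungapped alignment of cand against seed: best offset/orientation with
# >= min_matches matching bases, or NULL
align_kmer <- function(seed, cand, min_matches) {
  k <- nchar(seed)
  sv <- strsplit(seed, "")[[1]]
  best <- NULL
  for (orient in c("forward", "reverse_complement")) {
    cs <- if (orient == "forward") cand else revcomp(cand)
    cv <- strsplit(cs, "")[[1]]
    for (d in (-(k - 1L)):(k - 1L)) {
      i <- max(1L, 1L + d):min(k, k + d)       # seed positions overlapped
      matches <- sum(sv[i] == cv[i - d])
      if (matches >= min_matches && (is.null(best) || matches > best$matches)) {
        best <- list(offset = d, orientation = orient, matches = matches)
      }
    }
  }
  best
}

#' Assemble selected k-mers into motifs
#'
#' Greedy seeding by descending enrichment: each k-mer joins the first
#' existing group in which some already-stacked member aligns to it with
#' at least `k - 2` matching bases at some ungapped offset (either
#' orientation); its position in the group frame is the member's offset
#' composed with the alignment offset, so chains of overlapping k-mers
#' extend a group beyond the seed's own span. K-mers aligning to no group
#' seed a new one. Group members are stacked at their frame offsets and
#' per-column base frequencies become the motif matrix. Groups supported
#' by fewer than `min_kmer_support` k-mers are discarded as
#' low-complexity.
#'
#' @param selected_kmers `data.table` from [select_binding_kmers()].
#' @param min_kmer_support minimum k-mers per emitted motif (default 10).
#' @param name_prefix motif name prefix (typically the sample id).
#' @return list of [motif()] objects (source `"NoPeak"`).
#' @export
assemble_motifs <- function(selected_kmers, min_kmer_support = 10L,
                            name_prefix = "sample") {
  if (nrow(selected_kmers) == 0L) return(list())
  kmers <- selected_kmers$kmer
  k <- nchar(kmers[1])
  min_matches <- k - 2L
  # groups carry a running count matrix in a fixed frame; candidates align
  # against the group consensus (all members jointly), which is far more
  # stable than pairwise member alignment when variants share offsets
  groups <- list()
  add_member <- function(g, codes, offset) {
    lo_new <- min(g$lo, offset)
    hi_new <- max(g$hi, offset + k - 1L)
    if (lo_new < g$lo || hi_new > g$hi) {
      width <- hi_new - lo_new + 1L
      counts <- matrix(0, width, 4L)
      cover <- numeric(width)
      shift <- g$lo - lo_new
      counts[shift + seq_len(nrow(g$counts)), ] <- g$counts
      cover[shift + seq_len(nrow(g$counts))] <- g$coverage
      g$counts <- counts; g$coverage <- cover; g$lo <- lo_new; g$hi <- hi_new
    }
    rows <- offset - g$lo + 1L + 0:(k - 1L)
    g$counts[cbind(rows, codes)] <- g$counts[cbind(rows, codes)] + 1
    g$coverage[rows] <- g$coverage[rows] + 1
    g$support <- g$support + 1L
    g
  }
  for (km in kmers) {
    cand <- list(forward = encode_seq(km), reverse_complement = encode_seq(revcomp(km)))
    best <- NULL
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      freq <- g$counts / pmax(g$coverage, 1)
      for (orient in names(cand)) {
        codes <- cand[[orient]]
        for (d in (g$lo - 2L):(g$hi - k + 3L)) {  # overlap >= k - 2 columns
          cols <- d - g$lo + 1L + 0:(k - 1L)
          inside <- cols >= 1L & cols <= nrow(g$counts)
          if (sum(inside) < min_matches) next
          cc <- cols[inside]
          bb <- codes[inside]
          # expected matching bases under the group's frequency profile;
          # one-hot for a fresh group, so this generalises exact matching
          score <- sum(freq[cbind(cc, bb)])
          if (score < min_matches - 1e-9) next
          if (is.null(best) || score > best$score + 1e-12) {
            best <- list(gi = gi, score = score, offset = d, orient = orient)
          }
        }
      }
    }
    if (!is.null(best)) {
      groups[[best$gi]] <- add_member(groups[[best$gi]], cand[[best$orient]],
                                      best$offset)
    } else {
      g <- list(lo = 0L, hi = k - 1L, counts = matrix(0, k, 4L),
                coverage = numeric(k), support = 0L)
      groups[[length(groups) + 1L]] <- add_member(g, cand$forward, 0L)
    }
  }
  # merge pass: greedy joining is order-sensitive, so distinct groups can end
  # up holding different frames of the same motif; fuse groups whose
  # frequency profiles align (expected matches >= overlap - 2 over >= k - 2
  # shared columns), repeating to a fixed point
  rc_group <- function(g) {
    list(lo = -g$hi, hi = -g$lo,
         counts = g$counts[rev(seq_len(nrow(g$counts))), c(4L, 3L, 2L, 1L)],
         coverage = rev(g$coverage), support = g$support)
  }
  align_groups <- function(ga, gb) {
    fa <- ga$counts / pmax(ga$coverage, 1)
    best <- NULL
    for (orient in c("forward", "reverse_complement")) {
      gb2 <- if (orient == "forward") gb else rc_group(gb)
      fb <- gb2$counts / pmax(gb2$coverage, 1)
      for (d in (ga$lo - gb2$hi):(ga$hi - gb2$lo)) {
        ca <- max(ga$lo, gb2$lo + d):min(ga$hi, gb2$hi + d)
        ia <- ca - ga$lo + 1L
        ib <- ca - d - gb2$lo + 1L
        cov <- ga$coverage[ia] > 0 & gb2$coverage[ib] > 0
        if (sum(cov) < min_matches) next
        e <- sum(rowSums(fa[ia[cov], , drop = FALSE] *
                           fb[ib[cov], , drop = FALSE]))
        if (e < sum(cov) - 2 - 1e-9) next
        if (is.null(best) || e > best$e + 1e-12)
          best <- list(e = e, d = d, orient = orient)
      }
    }
    best
  }
  fuse <- function(ga, gb, al) {
    gb2 <- if (al$orient == "forward") gb else rc_group(gb)
    lo <- min(ga$lo, gb2$lo + al$d)
    hi <- max(ga$hi, gb2$hi + al$d)
    width <- hi - lo + 1L
    counts <- matrix(0, width, 4L)
    cover <- numeric(width)
    ia <- ga$lo - lo + seq_len(nrow(ga$counts))
    counts[ia, ] <- counts[ia, ] + ga$counts
    cover[ia] <- cover[ia] + ga$coverage
    ib <- gb2$lo + al$d - lo + seq_len(nrow(gb2$counts))
    counts[ib, ] <- counts[ib, ] + gb2$counts
    cover[ib] <- cover[ib] + gb2$coverage
    list(lo = lo, hi = hi, counts = counts, coverage = cover,
         support = ga$support + gb2$support)
  }
  repeat {
    merged <- FALSE
    gi <- 1L
    while (gi < length(groups)) {
      gj <- gi + 1L
      while (gj <= length(groups)) {
        al <- align_groups(groups[[gi]], groups[[gj]])
        if (!is.null(al)) {
          groups[[gi]] <- fuse(groups[[gi]], groups[[gj]], al)
          groups[[gj]] <- NULL
          merged <- TRUE
        } else gj <- gj + 1L
      }
      gi <- gi + 1L
    }
    if (!merged) break
  }
  out <- list()
  idx <- 0L
  for (g in groups) {
    if (g$support < min_kmer_support) next
    keep <- g$coverage > 0
    probs <- g$counts[keep, , drop = FALSE] / g$coverage[keep]
    idx <- idx + 1L
    out[[length(out) + 1L]] <- motif(
      sprintf("%s_motif_%d", name_prefix, idx - 1L), probs, source = "NoPeak",
      kmer_support = g$support, motif_class = "unclassified")
  }
  out
}
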