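#' De Bruijn sequence over ACGT
#'
#' Deterministic greedy (prefer-largest symbol) construction of a de Bruijn
#' sequence of order `k`: a linear sequence of length `4^k + k - 1`
#' containing every k-mer exactly once. Used as a neutral substrate on
#' which motif score profiles are compared, so similarity scores are
#' reproducible across runs and machines.
#'
#' @param k k-mer order (default 7).
#' @return character scalar.
#' @export
debruijn_sequence <- function(k = 7L) {
  key <- paste0("db", k)
  cached <- .asbmotif_cache[[key]]
  if (!is.null(cached)) return(cached)
  a <- 4L
  n <- a^k
  seen <- logical(n)
  out <- integer(n + k - 1L)
  out[1:k] <- 1L                       # start from A^k
  seen[1L] <- TRUE                     # code of A^k is 0 -> index 1
  suffix <- 0                          # base-4 code of the trailing (k-1)-mer
  len <- k
  amask <- a^(k - 1L)
  while (len < n + k - 1L) {
    placed <- FALSE
    for (c in (a - 1L):0L) {           # prefer largest symbol (T first)
      code <- suffix * a + c
      if (!seen[code + 1L]) {
        seen[code + 1L] <- TRUE
        len <- len + 1L
        out[len] <- c + 1L
        suffix <- code %% amask
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_fmt("asb_internal_error", "de Bruijn construction stalled at length %d", len)
  }
  s <- paste(.BASES[out], collapse = "")
  .asbmotif_cache[[key]] <- s
  s
}

# score profiles of a motif along the de Bruijn sequence and its reverse
# complement (two substrate blocks). Pooling both blocks makes the pairwise
# similarity exactly invariant to reverse-complementing both motifs. The
# matrix is regularised with a small pseudocount so motifs holding exact
# zeros (one-hot columns) still yield finite, correlatable profiles.
debruijn_profile <- function(m, k = 7L, background = rep(0.25, 4),
                             pseudocount = 0.01) {
  key <- paste0("dbcodes", k)
  codes <- .asbmotif_cache[[key]]
  if (is.null(codes)) {
    fwd <- encode_seq(debruijn_sequence(k))
    codes <- list(fwd = fwd, rc = rev(5L - fwd))
    .asbmotif_cache[[key]] <- codes
  }
  mm <- m
  mm$matrix <- (m$matrix + pseudocount) / (1 + 4 * pseudocount)
  lmat <- motif_logodds(mm, background)
  list(fwd = scan_codes(lmat, codes$fwd), rc = scan_codes(lmat, codes$rc))
}

#' Motif similarity on a de Bruijn sequence
#'
#' Both motifs are scored at every position of a fixed order-`k` de Bruijn
#' sequence and of its reverse complement (a strand-symmetric substrate),
#' and the Pearson correlation between the pooled score profiles is
#' computed at every integer offset `|d| < max(len_a, len_b)` and against
#' the reverse-complemented second motif; the maximum correlation is the
#' similarity score. Offsets are only considered when the profiles overlap
#' in at least `4^k / 2` positions per substrate block, preventing
#' spurious correlations from tiny overlaps.
#'
#' @param motif_a,motif_b [motif()] objects (length >= 4).
#' @param k de Bruijn order (default 7).
#' @param background base probabilities for the log-odds scoring.
#' @return list with `motif_a`, `motif_b` (names), `similarity`,
#'   `best_offset`, `best_orientation` (`"forward"` or
#'   `"reverse_complement"`).
#' @export
debruijn_similarity <- function(motif_a, motif_b, k = 7L,
                                background = rep(0.25, 4)) {
  pa <- debruijn_profile(motif_a, k, background)
  res <- list(similarity = -Inf, best_offset = 0L, best_orientation = "forward")
  min_overlap <- 4^k / 2
  max_off <- max(motif_length(motif_a), motif_length(motif_b)) - 1L
  for (orient in c("forward", "reverse_complement")) {
    mb <- if (orient == "forward") motif_b else revcomp_motif(motif_b)
    pb <- debruijn_profile(mb, k, background)
    na <- length(pa$fwd); nb <- length(pb$fwd)
    for (d in -max_off:max_off) {
      ia <- max(1L, 1L - d):min(na, nb - d)
      if (length(ia) < min_overlap) next
      xa <- c(pa$fwd[ia], pa$rc[ia])
      xb <- c(pb$fwd[ia + d], pb$rc[ia + d])
      if (!all(is.finite(xa)) || !all(is.finite(xb))) next
      if (sd(xa) == 0 || sd(xb) == 0) {
        r <- 0                              # degenerate flat profile
      } else r <- cor(xa, xb)
      if (r > res$similarity + 1e-12) {
        res$similarity <- r
        res$best_offset <- d
        res$best_orientation <- orient
      }
    }
  }
  if (!is.finite(res$similarity)) res$similarity <- 0
  list(motif_a = motif_a$name, motif_b = motif_b$name,
       similarity = res$similarity, best_offset = res$best_offset,
       best_orientation = res$best_orientation)
}

#' Cluster motifs by de Bruijn similarity
#'
#' Single-linkage agglomeration joining motifs with pairwise similarity
#' above `threshold`. Each multi-member cluster is represented by the
#' position-wise mean of its members after aligning them to the cluster
#' seed (the alphabetically first member name, making clustering stable
#' under input permutation) at their best offset and orientation;
#' positions a member does not cover are padded with the background
#' distribution before averaging. Representatives are named
#' `Average_<n>` from a deterministic counter; singleton clusters pass
#' through unchanged.
#'
#' @param motifs list of [motif()] objects (trim first via
#'   [trim_motif_edges()]).
#' @param threshold similarity threshold (default 0.7).
#' @param k de Bruijn order.
#' @param background base probabilities (also the padding distribution).
#' @return list of representative [motif()] objects.
#' @export
cluster_motifs <- function(motifs, threshold = 0.7, k = 7L,
                           background = rep(0.25, 4)) {
  n <- length(motifs)
  if (n == 0L) return(list())
  ord <- order(vapply(motifs, `[[`, character(1), "name"))
  motifs <- motifs[ord]
  if (n == 1L) return(motifs)
  sim <- matrix(list(), n, n)
  simval <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- debruijn_similarity(motifs[[i]], motifs[[j]], k, background)
    sim[[i, j]] <- s
    simval[i, j] <- simval[j, i] <- s$similarity
  }
  # connected components of the similarity-above-threshold graph
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (simval[i, j] > threshold && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- list()
  avg_counter <- 0L
  for (cl in unique(comp)) {
    members <- which(comp == cl)
    if (length(members) == 1L) {
      out[[length(out) + 1L]] <- motifs[[members]]
      next
    }
    seed <- members[1L]                 # alphabetically first (motifs sorted)
    pieces <- list(list(mat = motifs[[seed]]$matrix, off = 0L))
    for (mm in setdiff(members, seed)) {
      s <- if (seed < mm) sim[[seed, mm]] else sim[[mm, seed]]
      if (seed < mm) {
        mat <- if (s$best_orientation == "forward") motifs[[mm]]$matrix
               else revcomp_motif(motifs[[mm]])$matrix
        off <- s$best_offset
      } else {
        # stored as similarity(mm, seed): profile_mm[i] ~ profile_seed[i+d]
        mat <- if (s$best_orientation == "forward") motifs[[mm]]$matrix
               else revcomp_motif(motifs[[mm]])$matrix
        off <- -s$best_offset
      }
      pieces[[length(pieces) + 1L]] <- list(mat = mat, off = off)
    }
    lo <- min(vapply(pieces, `[[`, integer(1), "off"))
    hi <- max(vapply(pieces, function(p) p$off + nrow(p$mat) - 1L, integer(1)))
    width <- hi - lo + 1L
    stack <- array(rep(background, each = width), dim = c(width, 4L, length(pieces)))
    for (pi in seq_along(pieces)) {
      p <- pieces[[pi]]
      rows <- (p$off - lo + 1L):(p$off - lo + nrow(p$mat))
      stack[rows, , pi] <- p$mat
    }
    avg <- apply(stack, c(1L, 2L), mean)
    avg <- avg / rowSums(avg)
    avg_counter <- avg_counter + 1L
    support <- sum(vapply(motifs[members], function(m)
      if (is.na(m$kmer_support)) 0L else m$kmer_support, integer(1)))
    out[[length(out) + 1L]] <- motif(
      sprintf("Average_%d", avg_counter), avg, source = motifs[[seed]]$source,
      tf = motifs[[seed]]$tf,
      kmer_support = if (support > 0L) support else NA_integer_)
  }
  out
}

#' Classify a discovered motif against a JASPAR reference set
#'
#' Computes the de Bruijn similarity of the discovered motif to every
#' reference motif. If the best similarity exceeds `threshold` and the
#' best-matching reference motif belongs to the ChIPped (target) TF, the
#' motif is `redundant` (to be excluded downstream); if it exceeds
#' `threshold` only for motifs of other TFs it is `accessory`; otherwise it
#' is `de_novo`.
#'
#' @param nopeak_motif discovered [motif()].
#' @param jaspar_db nonempty list of reference motifs with `tf` labels.
#' @param target_tf the ChIPped TF.
#' @param threshold similarity threshold (default 0.7).
#' @param k de Bruijn order.
#' @return character scalar: `"redundant"`, `"accessory"` or `"de_novo"`.
#' @export
classify_nopeak_motif <- function(nopeak_motif, jaspar_db, target_tf,
                                  threshold = 0.7, k = 7L) {
  if (length(jaspar_db) == 0L)
    stop_fmt("asb_validation_error", "empty JASPAR reference set")
  sims <- vapply(jaspar_db, function(jm)
    debruijn_similarity(nopeak_motif, jm, k)$similarity, numeric(1))
  tfs <- vapply(jaspar_db, function(jm) as.character(jm$tf %||% NA), character(1))
  best <- which.max(sims)
  if (sims[best] > threshold && identical(tfs[best], target_tf)) return("redundant")
  if (any(sims > threshold & !is.na(tfs) & tfs != target_tf)) return("accessory")
  "de_novo"
}
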