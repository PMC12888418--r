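#' Build the pool of never-ASB, high-coverage SNPs
#'
#' The comparator pool contains tested SNPs that were never called ASB in
#' any cell line or TF, restricted to high pooled read coverage so the
#' absence of a call is informative.
#'
#' @param all_tested_snps SNP table (must carry `snp_id`; `maf` is needed
#'   downstream).
#' @param asb_calls call table(s) spanning every cell line/TF analysed
#'   (`snp_id`, `is_asb`).
#' @param counts allelic counts used to compute pooled coverage per SNP
#'   (optional if `all_tested_snps` already has a `total_reads` column).
#' @param min_reads minimum pooled reads (default 100; 50 is the lenient
#'   published alternative).
#' @return `data.table` of pool SNPs.
#' @export
build_nonasb_pool <- function(all_tested_snps, asb_calls, counts = NULL,
                              min_reads = 100L) {
  snps <- data.table::as.data.table(all_tested_snps)
  calls <- data.table::as.data.table(asb_calls)
  ever_asb <- unique(calls[is_asb == TRUE, snp_id])
  pool <- snps[!snp_id %in% ever_asb]
  if (!"total_reads" %in% names(pool)) {
    if (is.null(counts))
      stop_fmt("asb_validation_error",
               "need counts or a total_reads column to apply the coverage filter")
    cov <- data.table::as.data.table(counts)[
      , .(total_reads = sum(ref_count + alt_count)), by = snp_id]
    pool <- merge(pool, cov, by = "snp_id")
  }
  pool <- pool[total_reads >= min_reads]
  pool <- unique(pool, by = "snp_id")
  if (nrow(pool) == 0L)
    stop_fmt("asb_validation_error",
             "empty non-ASB pool; consider relaxing min_reads (e.g. 50)")
  pool[]
}

#' Sample MAF-matched comparator sets
#'
#' For each target SNP, candidates are pool SNPs whose minor allele
#' frequency lies within a relative tolerance of the target's
#' (`|maf_c - maf_t| <= rel_tol * maf_t`). Each of `n_sets` comparator
#' sets draws one candidate per target uniformly with replacement. The
#' median set takes, per target, the drawn candidate whose MAF is the
#' (lower) median of that target's draws.
#'
#' @param pool pool from [build_nonasb_pool()] (`snp_id`, `maf`).
#' @param targets target SNP table (`snp_id`, `maf`), e.g. the
#'   high-quality ASB set.
#' @param rel_tol relative MAF tolerance (default 0.05, i.e. 5%).
#' @param n_sets number of comparator sets (default 1000).
#' @param seed RNG seed; results are fully deterministic given it.
#' @return list of class `comparator_sets`: `target_ids`, `sampled_sets`
#'   (list of `n_sets` character vectors), `median_set`, `seed`.
#' @export
sample_maf_matched <- function(pool, targets, rel_tol = 0.05, n_sets = 1000L,
                               seed = 1L) {
  pool <- data.table::as.data.table(pool)
  targets <- data.table::as.data.table(targets)
  nt <- nrow(targets)
  cand <- lapply(seq_len(nt), function(i) {
    tol <- rel_tol * targets$maf[i]
    pool$snp_id[abs(pool$maf - targets$maf[i]) <= tol]
  })
  empty <- lengths(cand) == 0L
  if (any(empty))
    stop_fmt("asb_validation_error",
             "no MAF-matched pool candidates for targets: %s",
             paste(head(targets$snp_id[empty], 10), collapse = ", "))
  draws <- with_seed(seed, {
    lapply(seq_len(nt), function(i)
      cand[[i]][sample.int(length(cand[[i]]), n_sets, replace = TRUE)])
  })
  maf_map <- setNames(pool$maf, pool$snp_id)
  median_set <- vapply(seq_len(nt), function(i) {
    ids <- draws[[i]]
    ord <- order(maf_map[ids], ids)          # deterministic tie-break by id
    ids[ord[floor((n_sets + 1L) / 2L)]]      # lower median on even counts
  }, character(1))
  sampled_sets <- lapply(seq_len(n_sets), function(s)
    vapply(draws, `[[`, character(1), s))
  structure(list(target_ids = targets$snp_id, sampled_sets = sampled_sets,
                 median_set = median_set, seed = seed),
            class = "comparator_sets")
}

#' Empirical p-value against a resampled null
#'
#' Uses the positively biased estimator `(1 + r) / (1 + n)` where `r`
#' counts null statistics at least as extreme as the observation in the
#' requested tail.
#'
#' @param observed_stat scalar observed statistic.
#' @param null_stats numeric vector of null statistics (one per comparator
#'   set).
#' @param tail `"greater"` or `"less"`.
#' @return empirical p-value.
#' @export
empirical_pvalue <- function(observed_stat, null_stats, tail = c("greater", "less")) {
  tail <- match.arg(tail)
  if (length(null_stats) == 0L)
    stop_fmt("asb_validation_error", "empty null distribution")
  r <- if (tail == "greater") sum(null_stats >= observed_stat)
       else sum(null_stats <= observed_stat)
  (1 + r) / (1 + length(null_stats))
}

#' Count conserved and non-conserved SNPs
#'
#' Strict thresholds as published: conserved means PhastCons-style score
#' `> hi`, non-conserved means score `< lo`. Missing scores are excluded
#' and reported.
#'
#' @param snps table with a `conservation` (or `conservation_score`)
#'   column in `[0, 1]`.
#' @param hi,lo thresholds (defaults 0.95 and 0.05).
#' @return list `n_conserved`, `n_nonconserved`, `n_missing`.
#' @export
conservation_counts <- function(snps, hi = 0.95, lo = 0.05) {
  dt <- data.table::as.data.table(snps)
  col <- intersect(c("conservation", "conservation_score"), names(dt))[1]
  if (is.na(col))
    stop_fmt("asb_validation_error", "no conservation score column")
  x <- dt[[col]]
  miss <- is.na(x)
  if (any(x[!miss] < 0 | x[!miss] > 1))
    stop_fmt("asb_validation_error", "conservation scores outside [0,1]")
  list(n_conserved = sum(x[!miss] > hi),
       n_nonconserved = sum(x[!miss] < lo),
       n_missing = sum(miss))
}

# exact null distribution of the doubled rank sum of group A via DP over
# items: counts[t] = number of size-na subsets with doubled-rank total t
ranksum_exact_dist <- function(ranks2, na) {
  N <- length(ranks2)
  maxsum <- sum(sort(ranks2, decreasing = TRUE)[seq_len(na)])
  f <- matrix(0, na + 1L, maxsum + 1L)   # [count+1, sum+1]
  f[1L, 1L] <- 1
  for (r in ranks2) {
    upper <- min(na, N)
    for (cc in upper:1L) {
      src <- f[cc, ]
      if (r > 0) {
        shifted <- c(rep(0, r), src[seq_len(ncol(f) - r)])
        f[cc + 1L, ] <- f[cc + 1L, ] + shifted
      }
    }
  }
  f[na + 1L, ]
}

#' Wilcoxon rank sum (Mann-Whitney) test with exact small-sample p
#'
#' Mid-ranks handle ties. For groups of at most 20 each the two-sided
#' p-value is exact, from the full (tie-aware) permutation distribution of
#' the rank sum computed by dynamic programming; larger groups use the
#' normal approximation with tie correction.
#'
#' @param values_a,values_b numeric vectors (both nonempty).
#' @param exact_max largest per-group size for the exact route.
#' @return list with `statistic` (Mann-Whitney U for group A, mid-ranks)
#'   and `p_two_sided`.
#' @export
rank_sum_test <- function(values_a, values_b, exact_max = 20L) {
  na <- length(values_a); nb <- length(values_b)
  if (na == 0L || nb == 0L)
    stop_fmt("asb_validation_error", "both groups must be nonempty")
  all_v <- c(values_a, values_b)
  if (length(unique(all_v)) == 1L)
    return(list(statistic = na * nb / 2, p_two_sided = 1))
  rk <- rank(all_v, ties.method = "average")
  ra <- sum(rk[seq_len(na)])
  U <- ra - na * (na + 1) / 2
  if (na <= exact_max && nb <= exact_max) {
    ranks2 <- as.integer(round(2 * rk))
    dist <- ranksum_exact_dist(ranks2, na)
    total <- choose(na + nb, na)
    t_obs <- as.integer(round(2 * ra))
    center <- na * (na + nb + 1)          # doubled mean rank sum
    t_refl <- 2L * center - t_obs
    lo_t <- min(t_obs, t_refl); hi_t <- max(t_obs, t_refl)
    sums <- seq_len(length(dist)) - 1L
    p <- (sum(dist[sums <= lo_t]) + sum(dist[sums >= hi_t])) / total
    p <- min(1, p)
  } else {
    mu <- na * nb / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / ((na + nb) * (na + nb - 1))
    v <- na * nb / 12 * ((na + nb + 1) - tie_term)
    if (v <= 0) return(list(statistic = U, p_two_sided = 1))
    z <- (U - mu) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = U, p_two_sided = p)
}
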