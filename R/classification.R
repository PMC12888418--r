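# all permutations of 1..n as an n! x n integer matrix (n <= 9)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_perms(n - 1L)
  m <- nrow(p)
  out <- matrix(0L, m * n, n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * m + seq_len(m)
    out[rows, pos] <- n
    out[rows, -pos] <- p
  }
  out
}

#' Spearman concordance between CAR and MSD for one motif
#'
#' A motif is "high-quality" when the corrected allelic ratio and motif
#' score difference are positively and significantly correlated across the
#' in-peak heterozygous SNPs matching it: rho is the Pearson correlation of
#' mid-ranks (average-rank ties) and the two-sided p-value is exact (full
#' permutation enumeration) for n <= 9 and a t-approximation otherwise.
#'
#' @param car,msd numeric vectors of equal length (the CAR/MSD pairs,
#'   restricted upstream to SNPs with `matches = TRUE` and
#'   `in_peak = TRUE`).
#' @param min_snps minimum pairs for the screen (default 5; below that an
#'   exact two-sided permutation p-value cannot reach 0.05).
#' @param alpha significance level (default 0.05).
#' @return list with `n_snps`, `rho`, `pvalue`, `high_quality`, `reason`.
#' @export
spearman_car_msd <- function(car, msd, min_snps = 5L, alpha = 0.05) {
  stopifnot(length(car) == length(msd))
  n <- length(car)
  if (n < min_snps)
    return(list(n_snps = n, rho = NA_real_, pvalue = NA_real_,
                high_quality = FALSE,
                reason = sprintf("only %d SNPs (< %d)", n, min_snps)))
  rx <- rank(car, ties.method = "average")
  ry <- rank(msd, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0)
    return(list(n_snps = n, rho = NA_real_, pvalue = NA_real_,
                high_quality = FALSE, reason = "degenerate ranks"))
  rho <- cor(rx, ry)
  if (n <= 9L) {
    perms <- all_perms(n)
    cx <- rx - mean(rx)
    denom <- sqrt(sum(cx^2))
    # rho for every permutation of the y-ranks, vectorised
    ym <- matrix(ry[perms], nrow(perms), n)
    cy <- ym - mean(ry)
    rho_perm <- (cy %*% cx) / (denom * sqrt(rowSums(cy^2)))
    pvalue <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    pvalue <- 2 * pt(-abs(tt), n - 2)
  }
  list(n_snps = n, rho = rho, pvalue = pvalue,
       high_quality = rho > 0 && pvalue < alpha, reason = NA_character_)
}

#' Screen every motif for CAR-MSD concordance
#'
#' @param scores SNP-motif score table (rows from [score_het_snp()]).
#' @param calls ASB call table from [infer_asb_table()] (supplies CAR).
#' @param min_snps minimum in-peak matching SNPs per motif.
#' @return `data.table` with one row per motif: `motif`, `n_snps`, `rho`,
#'   `pvalue`, `high_quality`.
#' @export
motif_quality_table <- function(scores, calls, min_snps = 5L) {
  sc <- data.table::as.data.table(scores)
  merged <- merge(sc[matches == TRUE & in_peak == TRUE],
                  data.table::as.data.table(calls)[, .(snp_id, car)],
                  by = "snp_id")
  motifs <- unique(sc$motif)
  rows <- lapply(motifs, function(mn) {
    sub <- merged[motif == mn]
    q <- spearman_car_msd(sub$car, sub$msd, min_snps = min_snps)
    data.table::data.table(motif = mn, n_snps = q$n_snps, rho = q$rho,
                           pvalue = q$pvalue, high_quality = q$high_quality)
  })
  data.table::rbindlist(rows)
}

.CLASS_PRIORITY <- c(canonical = 1L, accessory = 2L, de_novo = 3L)

#' Classify one ASB call as High / Low / Unclassified
#'
#' Candidate motifs are the high-quality motifs the SNP matches whose
#' (CAR, MSD) pair is concordant: CAR > 0.5 with MSD > 0, or CAR < 0.5
#' with MSD < 0 (boundary values are not concordant). Attribution
#' prioritises JASPAR (canonical) motifs, then accessory, then de novo;
#' ties within a class break by `|MSD|` descending then motif name. The
#' call is High when the attributed SNP-motif score lies in a ChIP-seq
#' peak, Low otherwise, and Unclassified when no candidate exists.
#'
#' @param asb an `asb_call` (or one-row data.frame with `car`, `is_asb`);
#'   must be an ASB (`is_asb = TRUE`) - non-ASBs are never classified.
#' @param scores SNP-motif scores for this SNP, with a `motif_class`
#'   column (`canonical`/`accessory`/`de_novo`; redundant motifs must
#'   already be excluded).
#' @param qualities named logical vector (or motif-quality table) mapping
#'   motif name to `high_quality`.
#' @return list with `quality` (`High`/`Low`/`Unclassified`),
#'   `attributed_motif`, `attributed_class`.
#' @export
classify_asb <- function(asb, scores, qualities) {
  stopifnot(isTRUE(asb$is_asb))
  if (is.data.frame(qualities))
    qualities <- setNames(qualities$high_quality, qualities$motif)
  sc <- data.table::as.data.table(scores)
  if (nrow(sc) == 0L)
    return(list(quality = "Unclassified", attributed_motif = NA_character_,
                attributed_class = NA_character_))
  car <- asb$car
  hq <- qualities[sc$motif]
  hq[is.na(hq)] <- FALSE
  concordant <- (car > 0.5 & sc$msd > 0) | (car < 0.5 & sc$msd < 0)
  cand <- sc[hq & sc$matches & concordant]
  if (nrow(cand) == 0L)
    return(list(quality = "Unclassified", attributed_motif = NA_character_,
                attributed_class = NA_character_))
  pr <- .CLASS_PRIORITY[cand$motif_class]
  ord <- order(pr, -abs(cand$msd), cand$motif)
  top <- cand[ord[1]]
  list(quality = if (isTRUE(top$in_peak)) "High" else "Low",
       attributed_motif = top$motif,
       attributed_class = top$motif_class)
}

#' Classify every ASB in a call table
#'
#' @param calls table from [infer_asb_table()].
#' @param scores full SNP-motif score table with `motif_class`.
#' @param qualities motif-quality table from [motif_quality_table()].
#' @return `data.table`: calls joined with `quality`, `attributed_motif`,
#'   `attributed_class` (non-ASBs keep `quality = NA`).
#' @export
classify_asb_table <- function(calls, scores, qualities) {
  calls <- data.table::as.data.table(calls)
  sc <- data.table::as.data.table(scores)
  qual_map <- setNames(qualities$high_quality, qualities$motif)
  out <- data.table::copy(calls)
  out[, `:=`(quality = NA_character_, attributed_motif = NA_character_,
             attributed_class = NA_character_)]
  asb_rows <- which(out$is_asb)
  sc_split <- split(sc, by = "snp_id")
  for (i in asb_rows) {
    snp_scores <- sc_split[[out$snp_id[i]]]
    if (is.null(snp_scores)) snp_scores <- sc[0]
    cl <- classify_asb(out[i], snp_scores, qual_map)
    data.table::set(out, i, "quality", cl$quality)
    data.table::set(out, i, "attributed_motif", cl$attributed_motif)
    data.table::set(out, i, "attributed_class", cl$attributed_class)
  }
  out[]
}

#' Summarise classified ASBs over distinct TF-SNP pairs
#'
#' ASBs replicated across cell lines for the same TF-SNP pair are counted
#' once; a pair's reduced quality is High if High in any cell line, else
#' Low if Low anywhere, else Unclassified. Raw row counts (replicates
#' included) are also reported.
#'
#' @param classified table from [classify_asb_table()] (ASB rows only are
#'   counted; rows with `quality = NA` are ignored).
#' @return list with `n_rows`, `n_distinct`, `distinct_by_quality`,
#'   `rows_by_quality`, `per_tf` (distinct pairs per TF and quality).
#' @export
summarize_distinct <- function(classified) {
  dt <- data.table::as.data.table(classified)
  dt <- dt[!is.na(quality)]
  lv <- c("High", "Low", "Unclassified")
  if (nrow(dt) == 0L) {
    z <- setNames(rep(0L, 3L), lv)
    return(list(n_rows = 0L, n_distinct = 0L, distinct_by_quality = z,
                rows_by_quality = z,
                per_tf = data.table::data.table(tf = character(),
                                                quality = character(), n = integer())))
  }
  dt[, qrank := match(quality, lv)]
  red <- dt[, .(quality = lv[min(qrank)]), by = .(snp_id, tf)]
  list(n_rows = nrow(dt),
       n_distinct = nrow(red),
       distinct_by_quality = vapply(lv, function(q) sum(red$quality == q), integer(1)),
       rows_by_quality = vapply(lv, function(q) sum(dt$quality == q), integer(1)),
       per_tf = red[, .(n = .N), by = .(tf, quality)])
}
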