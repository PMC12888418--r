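test_that("uniform motif scores zero everywhere; one-hot scores are hand-computable", {
  unif <- motif("U", matrix(0.25, 5, 4), source = "JASPAR")
  sc <- logodds_scan(unif, random_seq(40, 1))
  expect_true(all(sc == 0))
  # one-hot ACGT on ACGT, uniform background: 4 * log2(1 / 0.25) = 8
  oh <- one_hot_motif("ACGT")
  sc2 <- logodds_scan(oh, "ACGT")
  expect_equal(sc2["+", 1], 8)
  expect_equal(logodds_scan(oh, "TTTT")["+", 1], -Inf)
  # N positions are excluded from maxima
  expect_equal(logodds_scan(oh, "ANGT")["+", 1], -Inf)
})

test_that("scan scores are strand-symmetric", {
  for (seed in 1:5) {
    m <- random_motif(6, seed)
    s <- random_seq(30, seed + 100)
    rc <- asbmotif:::revcomp(s)
    a <- logodds_scan(m, s)
    b <- logodds_scan(revcomp_motif(m), rc)
    # motif on sequence == reverse-complement motif on reverse-complement
    # sequence, with placements mirrored
    expect_equal(unname(a["+", ]), unname(rev(b["+", ])), tolerance = 1e-12)
    expect_equal(unname(a["-", ]), unname(rev(b["-", ])), tolerance = 1e-12)
  }
})

test_that("zero-probability background for a present base errors", {
  m <- random_motif(4, 2)
  expect_error(logodds_scan(m, "ACGT", background = c(0.5, 0.5, 0, 0)),
               class = "asb_config_error")
})

test_that("exact FPR threshold equals exhaustive enumeration", {
  m <- make_motif("ACGT", dom = 0.7, name = "T4")
  got <- fpr_threshold(m, fpr = 0.05, window_len = 6, method = "exact")
  # exhaustive oracle over all 4^6 windows
  g <- do.call(expand.grid, c(rep(list(c("A", "C", "G", "T")), 6),
                              stringsAsFactors = FALSE))
  best <- apply(g, 1, function(r) max(logodds_scan(m, paste(r, collapse = ""))))
  bs <- sort(best)
  expect_equal(got, bs[ceiling(0.95 * length(bs))])
  # fpr -> 1-eps gives the minimum possible best score
  expect_equal(fpr_threshold(m, fpr = 1 - 1e-9, window_len = 6, method = "exact"),
               min(best))
})

test_that("exact mode matches enumeration across motif and window sizes", {
  withr::with_seed(14, {
    for (cfg in list(c(4, 6), c(5, 7), c(6, 8))) {
      m <- random_motif(cfg[1], seed = cfg[1] * 10)
      for (fpr in c(0.05, 0.2)) {
        got <- fpr_threshold(m, fpr = fpr, window_len = cfg[2], method = "exact")
        g <- do.call(expand.grid, c(rep(list(c("A", "C", "G", "T")), cfg[2]),
                                    stringsAsFactors = FALSE))
        best <- sort(apply(g, 1, function(r)
          max(logodds_scan(m, paste(r, collapse = "")))))
        expect_equal(got, best[ceiling((1 - fpr) * length(best))],
                     tolerance = 1e-8)
      }
    }
  })
})

test_that("Monte-Carlo threshold is seed-deterministic and near exact", {
  m <- make_motif("ACGTAC", dom = 0.8)
  t1 <- fpr_threshold(m, window_len = 10, method = "mc", n_draws = 20000L, seed = 5)
  t2 <- fpr_threshold(m, window_len = 10, method = "mc", n_draws = 20000L, seed = 5)
  expect_identical(t1, t2)
  ex <- fpr_threshold(m, window_len = 10, method = "exact")
  expect_equal(t1, ex, tolerance = 0.15)
  expect_error(fpr_threshold(m, fpr = 0), class = "asb_config_error")
})

test_that("SNP scoring is antisymmetric under allele swap and matches brute force", {
  fx <- default_fixture()
  planted <- fx$motifs[[1]]
  snp <- fx$snps[planted == TRUE][1]
  r1 <- score_het_snp(planted, fx$genome, snp, fx$peaks, threshold = 0)
  swapped <- data.table::copy(snp)
  swapped[, c("ref", "alt") := .(alt, ref)]
  r2 <- score_het_snp(planted, fx$genome, swapped, fx$peaks, threshold = 0)
  expect_equal(r1$msd, -r2$msd)
  expect_equal(r1$ref_score, r2$alt_score)
  expect_true(r1$in_peak)

  # brute-force oracle: enumerate placements overlapping the SNP by hand
  chrom <- fx$genome[["chr1"]]
  flank <- 25L
  win <- substr(chrom, snp$pos - flank, snp$pos + flank)
  center <- flank + 1L
  brute <- function(allele) {
    w <- strsplit(win, "")[[1]]
    w[center] <- allele
    w <- paste(w, collapse = "")
    L <- nrow(planted$matrix)
    best <- -Inf
    for (i in seq_len(nchar(w) - L + 1L)) {
      if (!(i <= center && center <= i + L - 1L)) next
      sub <- substr(w, i, i + L - 1L)
      for (s in c(sub, asbmotif:::revcomp(sub))) {
        codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
        sc <- sum(log2(planted$matrix[cbind(seq_len(L), codes)] / 0.25))
        best <- max(best, sc)
      }
    }
    best
  }
  expect_equal(r1$ref_score, brute(snp$ref))
  expect_equal(r1$alt_score, brute(snp$alt))
})

test_that("SNPs far from any motif instance do not match at threshold", {
  fx <- default_fixture()
  planted <- fx$motifs[[1]]
  thr <- fpr_threshold(planted, fpr = 0.05, window_len = 51, method = "mc",
                       n_draws = 20000L, seed = 2)
  nulls <- fx$snps[planted == FALSE][1:10]
  res <- data.table::rbindlist(lapply(seq_len(nrow(nulls)), function(i)
    score_het_snp(planted, fx$genome, nulls[i], fx$peaks, threshold = thr)))
  expect_true(all(!res$in_peak))
  expect_lt(mean(res$matches), 0.5)   # most null windows fall below threshold
})

test_that("motif edge trimming strips low-IC columns but never below 4", {
  core <- make_motif("ACGTAC", dom = 0.95)$matrix
  mat <- rbind(rep(0.25, 4), core, rep(0.25, 4))
  m <- motif("pad", mat, source = "NoPeak")
  tr <- trim_motif_edges(m)
  expect_equal(nrow(tr$matrix), 6L)
  expect_equal(tr$matrix, core)
  oh <- one_hot_motif("ACGTACGT")
  expect_identical(trim_motif_edges(oh)$matrix, oh$matrix)
  # IC pattern (low, low, high x4, low): trimmed to the high-IC core
  weak <- matrix(c(0.3, 0.25, 0.25, 0.2), 1, 4)
  m2 <- motif("w", rbind(weak, weak, core[1:4, ], weak), source = "NoPeak")
  tr2 <- trim_motif_edges(m2)
  expect_equal(nrow(tr2$matrix), 4L)
  expect_equal(tr2$matrix, core[1:4, ])
  # all-uniform motif: trimming stops at the 4-column floor
  u <- motif("u", matrix(0.25, 8, 4), source = "NoPeak")
  expect_equal(nrow(trim_motif_edges(u)$matrix), 4L)
})

test_that("the de Bruijn sequence contains every k-mer exactly once", {
  for (k in c(3L, 5L)) {
    s <- debruijn_sequence(k)
    expect_equal(nchar(s), 4^k + k - 1)
    kms <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    expect_equal(length(unique(kms)), 4^k)
  }
})

test_that("similarity is reflexive, symmetric and reverse-complement aware", {
  withr::with_seed(33, {
    for (i in 1:8) {
      m <- random_motif(sample(5:10, 1), seed = 300 + i)
      expect_equal(debruijn_similarity(m, m)$similarity, 1, tolerance = 1e-9)
      rcres <- debruijn_similarity(m, revcomp_motif(m))
      expect_equal(rcres$similarity, 1, tolerance = 1e-9)
      expect_equal(rcres$best_orientation, "reverse_complement")
    }
    a <- random_motif(8, 501); b <- random_motif(7, 502)
    sab <- debruijn_similarity(a, b)$similarity
    sba <- debruijn_similarity(b, a)$similarity
    expect_equal(sab, sba, tolerance = 1e-9)
    expect_true(sab >= -1 && sab <= 1)
    # invariant to reverse-complementing both motifs
    srr <- debruijn_similarity(revcomp_motif(a), revcomp_motif(b))$similarity
    expect_equal(sab, srr, tolerance = 1e-9)
  })
})

test_that("dissimilar homopolymer motifs score low, checked independently", {
  pa <- one_hot_motif("AAAAAA")
  pc <- one_hot_motif("CCCCCC")
  res <- debruijn_similarity(pa, pc)
  expect_lt(res$similarity, 0.3)
  # independent recomputation at offset 0, forward, via direct correlation
  prof <- function(m) {
    s <- debruijn_sequence(7)
    codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    mat <- (m$matrix + 0.01) / 1.04
    L <- nrow(mat); n <- length(codes) - L + 1
    vapply(seq_len(n), function(i)
      sum(log2(mat[cbind(1:L, codes[i:(i + L - 1)])] / 0.25)), numeric(1))
  }
  direct <- cor(prof(pa), prof(pc))
  expect_lt(direct, 0.3)
  # the offset-0 forward correlation recomputed independently agrees
  expect_equal(res$similarity >= direct, TRUE)
})

test_that("clustering merges near-identical motifs and is permutation-stable", {
  m1 <- make_motif("TGACTCAG", dom = 0.9, name = "a1", source = "NoPeak")
  m2 <- make_motif("TGACTCAG", dom = 0.9, name = "a2", source = "NoPeak")
  reps <- cluster_motifs(list(m1, m2))
  expect_length(reps, 1L)
  expect_equal(reps[[1]]$matrix, m1$matrix, tolerance = 1e-9)
  far <- make_motif("CCCCGGGG", dom = 0.9, name = "b1", source = "NoPeak")
  reps2 <- cluster_motifs(list(m1, far))
  expect_length(reps2, 2L)
  # permutation stability: shuffling input order changes nothing
  withr::with_seed(4, {
    ms <- list(m1, m2, far,
               make_motif("TTGACTCA", dom = 0.85, name = "c1", source = "NoPeak"))
    r_fwd <- cluster_motifs(ms)
    r_shuf <- cluster_motifs(ms[c(3, 1, 4, 2)])
    nm <- function(l) sort(vapply(l, `[[`, character(1), "name"))
    expect_identical(nm(r_fwd), nm(r_shuf))
    for (n in nm(r_fwd)) {
      ma <- r_fwd[[which(vapply(r_fwd, `[[`, character(1), "name") == n)]]
      mb <- r_shuf[[which(vapply(r_shuf, `[[`, character(1), "name") == n)]]
      expect_equal(ma$matrix, mb$matrix, tolerance = 1e-12)
    }
  })
})

test_that("noisy copies of a planted PWM cluster into a faithful representative", {
  truth <- make_motif("TGACTCAGGT", dom = 0.88, name = "truth")
  withr::with_seed(21, {
    noisy <- lapply(1:3, function(i) {
      mat <- truth$matrix * 40
      mat <- mat + matrix(rgamma(length(mat), 1.2), nrow(mat), 4)
      mat <- mat / rowSums(mat)
      motif(paste0("noisy", i), mat, source = "NoPeak")
    })
    reps <- cluster_motifs(noisy)
    expect_length(reps, 1L)
    expect_match(reps[[1]]$name, "^Average_")
    expect_gt(debruijn_similarity(reps[[1]], truth)$similarity, 0.9)
  })
})

test_that("NoPeak motif classification follows the similarity and TF rules", {
  target <- make_motif("TGACTCAGGT", dom = 0.9, name = "JASPAR_target", tf = "TF1")
  other <- make_motif("CCGGAATTCC", dom = 0.9, name = "JASPAR_other", tf = "TF2")
  db <- list(target, other)
  same <- target; same$name <- "np1"; same$source <- "NoPeak"
  expect_equal(classify_nopeak_motif(same, db, "TF1"), "redundant")
  cop <- other; cop$name <- "np2"; cop$source <- "NoPeak"
  expect_equal(classify_nopeak_motif(cop, db, "TF1"), "accessory")
  lowic <- motif("np3", matrix(c(0.3, 0.25, 0.25, 0.2), 8, 4, byrow = TRUE),
                 source = "NoPeak")
  sims <- vapply(db, function(j) debruijn_similarity(lowic, j)$similarity,
                 numeric(1))
  expect_true(all(sims < 0.7))        # verified dissimilar database
  expect_equal(classify_nopeak_motif(lowic, db, "TF1"), "de_novo")
  expect_error(classify_nopeak_motif(same, list(), "TF1"),
               class = "asb_validation_error")
})
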