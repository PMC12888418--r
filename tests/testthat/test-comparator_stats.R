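test_that("non-ASB pool excludes ever-ASB SNPs and low-coverage sites", {
  snps <- data.table::data.table(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                                 maf = c(0.1, 0.2, 0.3, 0.4))
  calls <- data.table::data.table(
    snp_id = c("rs1", "rs1", "rs2", "rs3", "rs4"),
    cell_line = c("A", "B", "A", "A", "A"),
    is_asb = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  counts <- data.table::data.table(
    snp_id = rep(c("rs1", "rs2", "rs3", "rs4"), each = 2),
    replicate_id = rep(c("r1", "r2"), 4),
    ref_count = c(60, 60, 30, 30, 26, 24, 49, 50),
    alt_count = c(40, 40, 20, 19, 25, 24, 50, 51))
  # rs1 is ASB in one cell line: excluded despite coverage
  pool <- build_nonasb_pool(snps, calls, counts, min_reads = 99L)
  expect_setequal(pool$snp_id, c("rs2", "rs3", "rs4"))  # rs2: exactly 99 reads
  pool100 <- build_nonasb_pool(snps, calls, counts, min_reads = 100L)
  expect_setequal(pool100$snp_id, "rs4")          # 99 < 100 boundary
  pool50 <- build_nonasb_pool(snps, calls, counts, min_reads = 50L)
  expect_setequal(pool50$snp_id, c("rs2", "rs3", "rs4"))
  expect_error(build_nonasb_pool(snps, calls, counts, min_reads = 10000L),
               class = "asb_validation_error")
})

test_that("pool construction equals a brute-force filter on random fixtures", {
  withr::with_seed(81, {
    ids <- sprintf("rs%03d", 1:80)
    snps <- data.table::data.table(snp_id = ids, maf = runif(80, 0.01, 0.5))
    calls <- data.table::data.table(
      snp_id = sample(ids, 150, replace = TRUE),
      is_asb = runif(150) < 0.2)
    counts <- data.table::data.table(
      snp_id = rep(ids, each = 2), replicate_id = "r",
      ref_count = rpois(160, 40), alt_count = rpois(160, 40))
    pool <- build_nonasb_pool(snps, calls, counts, min_reads = 120L)
    cov <- tapply(counts$ref_count + counts$alt_count, counts$snp_id, sum)
    ever <- unique(calls$snp_id[calls$is_asb])
    want <- ids[!(ids %in% ever) & cov[ids] >= 120]
    expect_setequal(pool$snp_id, want)
  })
})

test_that("MAF matching uses the relative tolerance window", {
  pool <- data.table::data.table(snp_id = sprintf("p%d", 1:5),
                                 maf = c(0.19, 0.195, 0.21, 0.25, 0.05))
  targets <- data.table::data.table(snp_id = "t1", maf = 0.20)
  cs <- sample_maf_matched(pool, targets, rel_tol = 0.05, n_sets = 50, seed = 3)
  drawn <- unique(unlist(cs$sampled_sets))
  # candidate window is [0.19, 0.21]: p4 (0.25) and p5 (0.05) are excluded
  expect_true(all(drawn %in% c("p1", "p2", "p3")))
  # a target with no candidates is an error naming it
  t2 <- data.table::data.table(snp_id = c("t1", "t2"), maf = c(0.20, 0.45))
  expect_error(sample_maf_matched(pool, t2), "t2", class = "asb_validation_error")
})

test_that("a single candidate per target makes every set identical", {
  pool <- data.table::data.table(snp_id = c("p1", "p2"), maf = c(0.1, 0.4))
  targets <- data.table::data.table(snp_id = c("t1", "t2"), maf = c(0.1, 0.4))
  cs <- sample_maf_matched(pool, targets, n_sets = 20, seed = 9)
  for (s in cs$sampled_sets) expect_equal(s, c("p1", "p2"))
  expect_equal(cs$median_set, c("p1", "p2"))
})

test_that("draws are uniform over candidates and deterministic given a seed", {
  withr::with_seed(1, {
    pool <- data.table::data.table(snp_id = sprintf("p%d", 1:7),
                                   maf = rep(0.2, 7))
    targets <- data.table::data.table(snp_id = c("t1", "t2", "t3"),
                                      maf = rep(0.2, 3))
  })
  cs <- sample_maf_matched(pool, targets, n_sets = 101, seed = 13)
  cs2 <- sample_maf_matched(pool, targets, n_sets = 101, seed = 13)
  expect_identical(cs$sampled_sets, cs2$sampled_sets)
  expect_identical(cs$median_set, cs2$median_set)
  # per-target frequencies within 3 sigma of the uniform expectation
  for (t in 1:3) {
    draws <- vapply(cs$sampled_sets, `[[`, character(1), t)
    counts <- table(factor(draws, levels = pool$snp_id))
    expt <- 101 / 7
    sdev <- sqrt(101 * (1 / 7) * (6 / 7))
    expect_true(all(abs(counts - expt) <= 3 * sdev))
  }
  # every sampled candidate satisfies the tolerance window, exhaustively
  fx <- default_fixture()
  pool_fx <- fx$snps[101:200, .(snp_id, maf)]
  targ_fx <- fx$snps[1:10, .(snp_id, maf)]
  ok <- try(sample_maf_matched(pool_fx, targ_fx, rel_tol = 0.3, n_sets = 25,
                               seed = 2), silent = TRUE)
  if (!inherits(ok, "try-error")) {
    maf_map <- setNames(pool_fx$maf, pool_fx$snp_id)
    for (s in seq_along(ok$sampled_sets)) {
      got <- maf_map[ok$sampled_sets[[s]]]
      expect_true(all(abs(got - targ_fx$maf) <= 0.3 * targ_fx$maf))
    }
  }
})

test_that("empirical p-values follow the (1+r)/(1+n) estimator", {
  nulls <- 1:1000
  expect_equal(empirical_pvalue(2000, nulls, "greater"), 1 / 1001)
  expect_equal(empirical_pvalue(0, nulls, "less"), 1 / 1001)
  expect_equal(empirical_pvalue(5, rep(5, 100), "greater"), 1)
  # 7 of 1000 nulls at or above the observation: (7+1)/1001
  nulls7 <- c(rep(0, 993), rep(10, 7))
  expect_equal(empirical_pvalue(9, nulls7, "greater"), 8 / 1001)
  expect_equal(round(8 / 1001, 5), 0.00799)
  expect_error(empirical_pvalue(1, numeric(0)), class = "asb_validation_error")
})

test_that("conservation counts use strict thresholds and track missing", {
  snps <- data.frame(snp_id = 1:5,
                     conservation = c(0.96, 0.95, 0.04, 0.05, NA))
  got <- conservation_counts(snps)
  expect_equal(got$n_conserved, 1L)
  expect_equal(got$n_nonconserved, 1L)
  expect_equal(got$n_missing, 1L)
  allmid <- data.frame(conservation = rep(0.5, 10))
  expect_equal(conservation_counts(allmid)$n_conserved, 0L)
  expect_error(conservation_counts(data.frame(conservation = 1.2)),
               class = "asb_validation_error")
  withr::with_seed(5, {
    x <- data.frame(conservation = runif(200))
    got2 <- conservation_counts(x)
    expect_equal(got2$n_conserved, sum(x$conservation > 0.95))
    expect_equal(got2$n_nonconserved, sum(x$conservation < 0.05))
  })
})

test_that("rank-sum test is exact for small groups", {
  got <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$p_two_sided, 0.1)          # 2/20 orderings
  expect_equal(got$statistic, 0)
  same <- rank_sum_test(c(2, 2, 2), c(2, 2))
  expect_equal(same$p_two_sided, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), class = "asb_validation_error")
})

test_that("exact rank-sum p equals full enumeration, with and without ties", {
  withr::with_seed(90, {
    for (i in 1:3) {
      a <- rnorm(8); b <- rnorm(8, mean = 0.5)
      got <- rank_sum_test(a, b)
      expect_equal(got$p_two_sided, ranksum_enum_oracle(a, b))
    }
    a <- c(1, 2, 2, 3, 5, 5); b <- c(2, 3, 3, 5, 6, 7)
    expect_equal(rank_sum_test(a, b)$p_two_sided, ranksum_enum_oracle(a, b))
  })
})

test_that("large groups use a tie-corrected normal approximation", {
  withr::with_seed(91, {
    a <- rnorm(40); b <- rnorm(40, 1)
    got <- rank_sum_test(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-9)
  })
})

test_that("self-sampled 'observed' sets give roughly uniform empirical p", {
  # scaled-down calibration: 60 repetitions instead of 200
  fx <- default_fixture()
  pool <- fx$snps[, .(snp_id, maf, conservation)]
  withr::with_seed(17, {
    hits <- 0L
    n_rep <- 60L
    for (r in seq_len(n_rep)) {
      targ <- pool[sample(.N, 15)]
      cs <- sample_maf_matched(pool, targ, rel_tol = 0.5, n_sets = 60,
                               seed = 1000 + r)
      cons <- setNames(pool$conservation, pool$snp_id)
      obs <- sum(cons[targ$snp_id] > 0.8)
      nulls <- vapply(cs$sampled_sets, function(s) sum(cons[s] > 0.8), numeric(1))
      hits <- hits + (empirical_pvalue(obs, nulls, "greater") < 0.05)
    }
    expect_gte(hits / n_rep, 0)
    expect_lte(hits / n_rep, 0.12)
  })
})
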