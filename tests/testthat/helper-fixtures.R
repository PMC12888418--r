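# shared helpers and independent oracles; fixtures are cached so heavy ones
# build once per test run

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# quick PWM builder from a consensus string
make_motif <- function(consensus, dom = 0.85, name = consensus,
                       source = "JASPAR", tf = NA_character_) {
  codes <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  mat <- matrix((1 - dom) / 3, length(codes), 4)
  for (i in seq_along(codes)) mat[i, codes[i]] <- dom
  motif(name, mat, source = source, tf = tf)
}

one_hot_motif <- function(consensus, name = consensus) {
  codes <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  mat <- matrix(0, length(codes), 4)
  for (i in seq_along(codes)) mat[i, codes[i]] <- 1
  motif(name, mat, source = "JASPAR")
}

random_motif <- function(len, seed, name = paste0("rand", seed)) {
  withr::with_seed(seed, {
    mat <- matrix(rgamma(len * 4, shape = 0.8), len, 4)
    mat <- mat / rowSums(mat)
    motif(name, mat, source = "JASPAR")
  })
}

random_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# --- independent oracles -------------------------------------------------

# posterior median of beta on a dense grid, exact binomial likelihood with
# the odds-composition theta; flat prior
grid_posterior_median <- function(ref, alt, raf, b, n_grid = 10001L) {
  beta <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  theta <- beta * raf * b / (beta * raf * b + (1 - beta) * (1 - raf) * (1 - b))
  ll <- ref * log(theta) + alt * log(1 - theta)
  w <- exp(ll - max(ll))
  cw <- cumsum(w) / sum(w)
  beta[which(cw >= 0.5)[1]]
}

# exact HPD of a Beta(a, b) distribution by minimising interval width over
# the lower tail probability
beta_hpd_exact <- function(a, b, level = 0.95) {
  f <- function(p1) qbeta(p1 + level, a, b) - qbeta(p1, a, b)
  opt <- optimize(f, c(0, 1 - level), tol = 1e-10)
  c(qbeta(opt$minimum, a, b), qbeta(opt$minimum + level, a, b))
}

# recursive permutation generator, independent of the package's all_perms
perm_list <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perm_list(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# exact two-sided Spearman permutation p via explicit loop over permutations
spearman_perm_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  perms <- perm_list(seq_along(y))
  rhos <- vapply(perms, function(p) cor(rx, ry[p]), numeric(1))
  list(rho = rho, pvalue = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# exact two-sided rank-sum p by full subset enumeration
ranksum_enum_oracle <- function(a, b) {
  va <- c(a, b)
  n <- length(va); na <- length(a)
  rk <- rank(va)
  obs <- sum(rk[seq_len(na)])
  combs <- combn(n, na)
  sums <- apply(combs, 2, function(ix) sum(rk[ix]))
  center <- na * (n + 1)              # doubled mean, keep halves exact
  lo <- min(obs, center - obs); hi <- max(obs, center - obs)
  min(1, (sum(sums <= lo) + sum(sums >= hi)) / ncol(combs))
}

# --- alignment fixture ---------------------------------------------------

# write a SAM programmatically, convert to sorted+indexed BAM; reads is a
# data.frame with qname, flag, pos, seq
write_test_bam <- function(reads, dir, chrom = "chr1", chrom_len = 10000L,
                           name = "t") {
  sam <- file.path(dir, paste0(name, ".sam"))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  reads <- reads[order(reads$pos), , drop = FALSE]
  recs <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, chrom, reads$pos,
                  nchar(reads$seq), reads$seq,
                  vapply(nchar(reads$seq), function(n) strrep("I", n), ""))
  writeLines(c(hdr, recs), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, name), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# --- shared fixtures -----------------------------------------------------

default_fixture <- function() {
  cached("default_fx", generate_fixture(fixture_spec(seed = 101)))
}

discovery_fixture <- function() {
  cached("discovery_fx",
         generate_fixture(fixture_spec(seed = 202, genome_len = 100000L,
                                       n_motif_sites = 300L, n_snps = 40L,
                                       n_planted_asb = 15L)))
}
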