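#' Model configuration for ASB inference
#'
#' @param rm_bias_b reference-mapping bias, the probability that a read from
#'   a balanced site maps to the REF allele; in (0,1), 0.5 = unbiased.
#' @param dispersion_phi beta-binomial overdispersion in `[0, 1)`; 0 reduces
#'   the replicate likelihood to binomial.
#' @param n_iter Metropolis-Hastings iterations.
#' @param n_burnin burn-in iterations discarded before summarisation.
#' @param hpd_level credible level of the highest-posterior-density interval
#'   used for calling (default 0.95, matching the published workflow).
#' @param step standard deviation of the Gaussian random walk on
#'   `logit(beta)`.
#' @param seed RNG seed making every call deterministic.
#' @return a `model_config` list.
#' @export
model_config <- function(rm_bias_b = 0.5, dispersion_phi = 0, n_iter = 5000L,
                         n_burnin = 1000L, hpd_level = 0.95, step = 0.3,
                         seed = 1234L) {
  stopifnot(rm_bias_b > 0, rm_bias_b < 1, dispersion_phi >= 0, dispersion_phi < 1,
            n_burnin < n_iter, hpd_level > 0, hpd_level < 1, step > 0)
  structure(list(rm_bias_b = rm_bias_b, dispersion_phi = dispersion_phi,
                 n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
                 hpd_level = hpd_level, step = step, seed = as.integer(seed)),
            class = "model_config")
}

#' Convert a mean background allelic dosage (BAD) to a RAF
#'
#' External copy-number resources summarise imbalance as BAD; the equivalent
#' reference allele frequency is `1 / (mean_bad + 1)`.
#'
#' @param mean_bad nonnegative mean BAD.
#' @return RAF in (0, 1].
#' @export
raf_from_bad <- function(mean_bad) {
  if (any(mean_bad < 0)) stop_fmt("asb_validation_error", "mean_bad must be >= 0")
  1 / (mean_bad + 1)
}

#' Estimate reference-mapping bias from pooled allelic counts
#'
#' The RM bias b is estimated as the trimmed mean of per-SNP REF-read
#' fractions over SNPs with adequate pooled coverage. With fewer than 20
#' eligible SNPs the estimator is unstable and 0.5 is returned (with a
#' warning).
#'
#' @param counts allelic counts (data.frame with `snp_id`, `ref_count`,
#'   `alt_count`; replicates are pooled per SNP).
#' @param trim_fraction fraction trimmed from each tail.
#' @param min_total minimum pooled reads for a SNP to be eligible.
#' @return scalar estimate of b.
#' @export
estimate_rm_bias <- function(counts, trim_fraction = 0.1, min_total = 10) {
  if (is.null(counts) || nrow(counts) == 0L) {
    warning("no counts supplied; falling back to rm_bias_b = 0.5")
    return(0.5)
  }
  dt <- data.table::as.data.table(counts)
  pooled <- dt[, .(ref = sum(ref_count), alt = sum(alt_count)), by = snp_id]
  pooled <- pooled[ref + alt >= min_total]
  if (nrow(pooled) < 20L) {
    warning(sprintf("only %d SNPs with >= %d reads; falling back to rm_bias_b = 0.5",
                    nrow(pooled), min_total))
    return(0.5)
  }
  mean(pooled$ref / (pooled$ref + pooled$alt), trim = trim_fraction)
}

# REF-read probability: latent balance beta composed with RAF and RM bias
# on the odds scale. Reduces to theta = beta at raf = b = 0.5.
compose_theta <- function(beta, raf, b) {
  num <- beta * raf * b
  num / (num + (1 - beta) * (1 - raf) * (1 - b))
}

#' Shortest highest-posterior-density interval from samples
#'
#' The HPD is the shortest contiguous window of `ceiling(level * n)` sorted
#' samples; ties are broken by the earliest window.
#'
#' @param samples numeric vector of at least 100 posterior draws in (0,1).
#' @param level credible level in (0,1).
#' @return numeric `c(lo, hi)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  n <- length(samples)
  if (n < 100L)
    stop_fmt("asb_validation_error", "need >= 100 samples for a stable HPD (got %d)", n)
  s <- sort(samples)
  m <- ceiling(level * n)
  if (m >= n) return(c(s[1], s[n]))
  k <- n - m + 1L
  widths <- s[m:n] - s[1:k]
  i <- which.min(widths)            # which.min takes the earliest tie
  c(s[i], s[i + m - 1L])
}

# random-walk MH on logit(beta); returns post-burn-in beta samples and the
# acceptance rate. Likelihood: beta-binomial(n_j, theta, phi) per replicate,
# binomial when phi = 0; flat Beta(1,1) prior on beta.
mh_sample_beta <- function(refs, alts, raf, b, phi, n_iter, n_burnin, step, seed) {
  c1 <- raf * b
  c0 <- (1 - raf) * (1 - b)
  R <- sum(refs); A <- sum(alts)
  use_bb <- phi > 0
  if (use_bb) nu <- (1 - phi) / phi   # theta*nu, (1-theta)*nu are BB shape pars
  loglik <- function(x) {
    bet <- 1 / (1 + exp(-x))
    th <- bet * c1 / (bet * c1 + (1 - bet) * c0)
    lp <- log(bet) + log1p(-bet)      # flat prior on beta + logit Jacobian
    if (!use_bb) return(R * log(th) + A * log1p(-th) + lp)
    a1 <- th * nu; a2 <- (1 - th) * nu
    sum(lbeta(refs + a1, alts + a2)) - length(refs) * lbeta(a1, a2) + lp
  }
  with_seed(seed, {
    prop <- rnorm(n_iter, 0, step)
    lu <- log(runif(n_iter))
    x <- 0
    ll <- loglik(x)
    out <- numeric(n_iter)
    acc <- 0L
    for (i in seq_len(n_iter)) {
      xn <- x + prop[i]
      lln <- loglik(xn)
      if (lln - ll > lu[i]) {
        x <- xn; ll <- lln; acc <- acc + 1L
      }
      out[i] <- x
    }
    list(beta = 1 / (1 + exp(-out[(n_burnin + 1L):n_iter])),
         acceptance = acc / n_iter)
  })
}

#' Infer allele-specific binding at one SNP
#'
#' Fits the latent allelic balance beta (flat Beta(1,1) prior) where each
#' replicate's REF-read probability is the odds composition
#' `theta = beta*raf*b / (beta*raf*b + (1-beta)*(1-raf)*(1-b))` with RM bias
#' `b`, so RAF (copy number) and b act as pure nuisance multipliers on the
#' odds scale. Sampling is random-walk Metropolis-Hastings on
#' `logit(beta)`. The corrected allelic ratio (CAR) is the posterior
#' median; a SNP is called ASB when the HPD interval at
#' `config$hpd_level` excludes 0.5.
#'
#' @param counts allelic counts for one SNP: data.frame with `ref_count`,
#'   `alt_count` per replicate (and optionally `snp_id`, `replicate_id`).
#' @param raf reference allele frequency at the SNP, strictly inside (0,1).
#' @param config a [model_config()].
#' @param snp_id,tf,cell_line labels carried into the call record.
#' @return an `asb_call` list with fields `snp_id`, `tf`, `cell_line`,
#'   `car`, `hpd_lo`, `hpd_hi`, `is_asb`, `total_counts`, `acceptance`,
#'   `converged`.
#' @export
infer_asb <- function(counts, raf, config = model_config(),
                      snp_id = NA_character_, tf = NA_character_,
                      cell_line = NA_character_) {
  if (raf <= 0 || raf >= 1)
    stop_fmt("asb_validation_error",
             "raf = %g is not compatible with a heterozygous site", raf)
  refs <- as.numeric(counts$ref_count)
  alts <- as.numeric(counts$alt_count)
  if (length(refs) < 1L || any(refs + alts < 1))
    stop_fmt("asb_validation_error", "each replicate needs >= 1 read")
  res <- mh_sample_beta(refs, alts, raf, config$rm_bias_b, config$dispersion_phi,
                        config$n_iter, config$n_burnin, config$step, config$seed)
  hpd <- hpd_interval(res$beta, config$hpd_level)
  converged <- res$acceptance >= 0.05 && res$acceptance <= 0.8
  if (!converged)
    warning(sprintf("SNP %s: MH acceptance rate %.3f outside [0.05, 0.8]",
                    snp_id, res$acceptance))
  structure(list(snp_id = snp_id, tf = tf, cell_line = cell_line,
                 car = median(res$beta), hpd_lo = hpd[1], hpd_hi = hpd[2],
                 is_asb = hpd[2] < 0.5 || hpd[1] > 0.5,
                 total_counts = sum(refs + alts),
                 acceptance = res$acceptance, converged = converged),
            class = "asb_call")
}

#' @export
print.asb_call <- function(x, ...) {
  cat(sprintf("<asb_call %s> CAR=%.3f HPD=[%.3f, %.3f] isASB=%s n=%d\n",
              x$snp_id, x$car, x$hpd_lo, x$hpd_hi, x$is_asb, x$total_counts))
  invisible(x)
}

#' Infer ASB across a table of SNPs
#'
#' Runs [infer_asb()] per SNP with a per-SNP seed derived deterministically
#' from `config$seed`, so the full table is reproducible.
#'
#' @param counts allelic-count table ([read_allelic_counts()]).
#' @param snps heterozygous SNP table ([read_het_snps()]) supplying per-SNP
#'   RAF; SNPs with no counts are skipped.
#' @param config a [model_config()].
#' @param tf,cell_line labels for the emitted calls.
#' @return `data.table` of calls, one row per SNP, mirroring the columns
#'   `snp_id`, `tf`, `cell_line`, `car`, `hpd_lo`, `hpd_hi`, `is_asb`,
#'   `total_counts`.
#' @export
infer_asb_table <- function(counts, snps, config = model_config(),
                            tf = NA_character_, cell_line = NA_character_) {
  counts <- data.table::as.data.table(counts)
  snps <- data.table::as.data.table(snps)
  ids <- intersect(unique(snps$snp_id), unique(counts$snp_id))
  raf_map <- setNames(snps$raf, snps$snp_id)
  rows <- vector("list", length(ids))
  split_counts <- split(counts, by = "snp_id", keep.by = TRUE)
  for (i in seq_along(ids)) {
    id <- ids[i]
    cfg <- config
    cfg$seed <- (config$seed + i) %% .Machine$integer.max
    call <- infer_asb(split_counts[[id]], raf_map[[id]], cfg,
                      snp_id = id, tf = tf, cell_line = cell_line)
    rows[[i]] <- data.table::data.table(
      snp_id = id, tf = tf, cell_line = cell_line, car = call$car,
      hpd_lo = call$hpd_lo, hpd_hi = call$hpd_hi, is_asb = call$is_asb,
      total_counts = call$total_counts, converged = call$converged)
  }
  data.table::rbindlist(rows)
}

#' Method-of-moments beta-binomial overdispersion across replicates
#'
#' Returns 0 when fewer than 3 replicates are available (a stable
#' moment estimate needs at least 3 REF-fraction observations).
#'
#' @param counts data.frame with `ref_count`, `alt_count`, one row per
#'   replicate at one SNP.
#' @return phi estimate in `[0, 1)`.
#' @export
estimate_dispersion <- function(counts) {
  n <- counts$ref_count + counts$alt_count
  J <- length(n)
  if (J < 3L) return(0)
  p <- counts$ref_count / n
  pbar <- sum(counts$ref_count) / sum(n)
  if (pbar <= 0 || pbar >= 1) return(0)
  # Var(p_j) = pbar(1-pbar) * (1 + (n_j - 1) phi) / n_j; solve for phi from
  # the observed variance of the replicate REF fractions.
  s2 <- stats::var(p)
  m1 <- mean(1 / n)
  phi <- (s2 / (pbar * (1 - pbar)) - m1) / (1 - m1)
  max(0, min(phi, 0.99))
}
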