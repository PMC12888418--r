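#' Draw allelic counts from the generative ASB model
#'
#' Inverse of [infer_asb()]: composes the REF-read probability
#' `theta = beta*raf*b / (beta*raf*b + (1-beta)*(1-raf)*(1-b))` and draws
#' `n_reads` as beta-binomial(theta, phi), reducing to binomial at
#' `phi = 0`.
#'
#' @param beta latent allelic balance in (0,1).
#' @param raf reference allele frequency in (0,1).
#' @param b reference-mapping bias in (0,1).
#' @param phi overdispersion in `[0,1)`.
#' @param n_reads total reads (>= 1).
#' @param seed optional seed (NULL uses the current RNG stream).
#' @return integer `c(ref_count, alt_count)`.
#' @export
simulate_counts <- function(beta, raf, b = 0.5, phi = 0, n_reads, seed = NULL) {
  if (n_reads < 1L) stop_fmt("asb_validation_error", "n_reads must be >= 1")
  stopifnot(beta > 0, beta < 1, raf > 0, raf < 1, b > 0, b < 1, phi >= 0, phi < 1)
  draw <- function() {
    theta <- compose_theta(beta, raf, b)
    p <- if (phi > 0) {
      nu <- (1 - phi) / phi
      rbeta(1L, theta * nu, (1 - theta) * nu)
    } else theta
    r <- rbinom(1L, n_reads, p)
    c(ref_count = r, alt_count = n_reads - r)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# built-in planted PWM: 12 columns, dominant base probability `dom`, with two
# 50/50 degenerate columns at positions 5 and 8. Both degenerate columns lie
# inside every 8-mer window of the motif, so each window has four frequent
# k-mer variants; that is what lets one assembled k-mer group reach the
# 10-k-mer support floor at realistic occurrence counts (~300 planted sites).
default_planted_motif <- function(dom = 0.94) {
  cons <- c("T", "G", "T", "T", "T", "A", "C", "T", "T", "A", "G", "C")
  mat <- matrix((1 - dom) / 3, length(cons), 4L, dimnames = list(NULL, .BASES))
  for (i in seq_along(cons)) mat[i, cons[i]] <- dom
  mat[5L, ] <- 0; mat[5L, c("T", "C")] <- 0.5
  mat[8L, ] <- 0; mat[8L, c("T", "G")] <- 0.5
  motif("planted_TF1", mat, source = "JASPAR", tf = "TF1",
        motif_class = "canonical")
}

#' Specification of a synthetic fixture
#'
#' The stated world of the generator: a random genome with motif
#' instances planted inside declared peaks, heterozygous SNPs planted at
#' high-information motif columns with the ALT allele chosen to maximise
#' `|MSD|`, true allelic balance tied to the motif disruption through a
#' logistic effect map `beta = plogis(effect_slope * MSD)` (so CAR-MSD
#' concordance holds by construction), and null SNPs at `beta = 0.5`
#' outside peaks. Counts are drawn from the same generative model the
#' inference assumes.
#'
#' @param genome_len genome length in bp.
#' @param n_snps total SNPs.
#' @param n_planted_asb SNPs planted at motif columns with
#'   motif-disrupting alleles.
#' @param planted_motif the planted PWM ([motif()]);
#'   default [default_planted_motif()].
#' @param effect_slope logistic slope of the MSD -> beta effect map.
#' @param coverage_mean mean reads per replicate per SNP (Poisson).
#' @param raf_distortion fraction of SNPs given RAF != 0.5 (CNV mimic;
#'   distorted SNPs draw RAF from {0.25, 0.75}).
#' @param rm_bias_true true reference-mapping bias.
#' @param dispersion_phi true overdispersion.
#' @param n_replicates replicates per SNP.
#' @param n_motif_sites additional read-only motif instances (used when
#'   reads are generated, to power k-mer discovery).
#' @param reads_per_site,n_background_reads read counts for the optional
#'   read-level output.
#' @param seed RNG seed; identical specs produce byte-identical bundles.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(genome_len = 20000L, n_snps = 200L, n_planted_asb = 30L,
                         planted_motif = default_planted_motif(),
                         effect_slope = 0.6, coverage_mean = 80L,
                         raf_distortion = 0.3, rm_bias_true = 0.5,
                         dispersion_phi = 0, n_replicates = 2L,
                         n_motif_sites = 0L, reads_per_site = 40L,
                         n_background_reads = 2000L, seed = 1L) {
  stopifnot(n_planted_asb <= n_snps, coverage_mean >= 20)
  structure(list(genome_len = as.integer(genome_len), n_snps = as.integer(n_snps),
                 n_planted_asb = as.integer(n_planted_asb),
                 planted_motif = planted_motif, effect_slope = effect_slope,
                 coverage_mean = coverage_mean, raf_distortion = raf_distortion,
                 rm_bias_true = rm_bias_true, dispersion_phi = dispersion_phi,
                 n_replicates = as.integer(n_replicates),
                 n_motif_sites = as.integer(n_motif_sites),
                 reads_per_site = as.integer(reads_per_site),
                 n_background_reads = as.integer(n_background_reads),
                 seed = as.integer(seed)), class = "fixture_spec")
}

# sample a site sequence from the PWM
sample_site <- function(mat) {
  vapply(seq_len(nrow(mat)), function(i)
    sample(.BASES, 1L, prob = mat[i, ]), character(1))
}

#' Generate a complete synthetic fixture bundle
#'
#' Writes (when `dir` is given) and returns a miniature dataset exercising
#' every pipeline stage: genome FASTA, peak BED, heterozygous SNP TSV with
#' annotations, per-replicate allelic-count TSV, a JASPAR-format motif file
#' (planted motif as the target TF's canonical motif plus decoys), an
#' optional BED6 read set, and a truth table recording every latent
#' quantity.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (NULL returns in-memory objects only).
#' @param make_reads also generate read intervals around motif sites.
#' @return list with elements `genome` (named character), `snps`, `counts`,
#'   `peaks_df`, `truth`, `motifs`, `reads` (or NULL), and `paths` when
#'   written.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL,
                             make_reads = spec$n_motif_sites > 0L) {
  pm <- spec$planted_motif
  L <- motif_length(pm)
  with_seed(spec$seed, {
    glen <- spec$genome_len
    genome_v <- sample(.BASES, glen, replace = TRUE)
    n_sites <- spec$n_planted_asb + spec$n_motif_sites
    # sites spaced beyond the read-offset spread (~±100 bp plus read length),
    # so a k-mer occurrence sees its own site's reads, not its neighbours'
    spacing <- max(300L, min(600L, (glen - 400L - L) %/% (n_sites + 1L)))
    grid <- seq(200L, glen - 200L - L, by = spacing)
    if (length(grid) < n_sites)
      stop_fmt("asb_validation_error",
               "genome too short for %d motif sites (room for %d)",
               n_sites, length(grid))
    sites <- if (n_sites > 0L) sort(sample(grid, n_sites)) else integer(0)
    for (s in sites) genome_v[s:(s + L - 1L)] <- sample_site(pm$matrix)

    # peaks around every planted site (0-based half-open BED)
    peaks_df <- data.frame(chrom = rep("chr1", n_sites),
                           start = pmax(0L, sites - 81L),
                           end = sites + L + 80L)
    peaks <- read_bed_peaks(peaks_df, tf = "TF1", cell_line = "cellA")

    # planted SNPs at the highest-IC column of the first n_planted_asb sites
    ic <- motif_ic(pm)
    snp_col <- which.max(ic)
    strong <- which.max(pm$matrix[snp_col, ])
    weak <- which.min(pm$matrix[snp_col, ])
    planted_sites <- if (spec$n_planted_asb > 0L)
      sort(sample(sites, spec$n_planted_asb)) else integer(0)
    planted_pos <- planted_sites + snp_col - 1L
    up <- if (spec$n_planted_asb > 0L)
      sample(c(TRUE, FALSE), spec$n_planted_asb, replace = TRUE) else logical(0)
    # up = TRUE: REF is the strong base (MSD > 0, beta > 0.5)
    genome_v[planted_pos] <- .BASES[ifelse(up, strong, weak)]
    planted_ref <- .BASES[ifelse(up, strong, weak)]
    planted_alt <- .BASES[ifelse(up, weak, strong)]

    # null SNPs outside peaks and away from motif sites
    n_null <- spec$n_snps - spec$n_planted_asb
    null_pos <- integer(0)
    taken <- c(planted_pos)
    while (length(null_pos) < n_null) {
      cand <- sample(seq(30L, glen - 30L), n_null * 2L, replace = FALSE)
      cand <- cand[!peaks_contain(peaks, "chr1", cand)]
      cand <- cand[!cand %in% taken]
      cand <- cand[!duplicated(cand)]
      null_pos <- head(c(null_pos, cand), n_null)
      taken <- c(taken, null_pos)
    }
    null_pos <- sort(null_pos)
    null_ref <- genome_v[null_pos]
    null_alt <- vapply(null_ref, function(r)
      sample(setdiff(.BASES, r), 1L), character(1))

    genome <- c(chr1 = paste(genome_v, collapse = ""))
    pos <- c(planted_pos, null_pos)
    ord <- order(pos)
    snps <- data.table::data.table(
      snp_id = sprintf("rs%05d", seq_along(pos)),
      chrom = "chr1",
      pos = pos[ord],
      ref = c(planted_ref, null_ref)[ord],
      alt = c(planted_alt, null_alt)[ord],
      genotype_quality = round(runif(length(pos), 0.96, 1.0), 4),
      cell_line = "cellA",
      planted = c(rep(TRUE, spec$n_planted_asb), rep(FALSE, n_null))[ord])
    # RAF: distorted fraction mimics copy-number aberration
    n_tot <- nrow(snps)
    distorted <- sample.int(n_tot, round(spec$raf_distortion * n_tot))
    raf <- rep(0.5, n_tot)
    raf[distorted] <- sample(c(0.25, 0.75), length(distorted), replace = TRUE)
    snps[, raf := raf]
    snps[, maf := round(0.5 * rbeta(n_tot, 1.2, 3), 4)]
    snps[, ancestral_allele := ifelse(runif(n_tot) < 0.8, ref, alt)]
    snps[, conservation := round(runif(n_tot), 4)]

    # true MSD from the planted motif on the written genome; effect map
    truth <- data.table::copy(snps[, .(snp_id, chrom, pos, ref, alt, raf, planted)])
    msd_true <- vapply(seq_len(n_tot), function(i) {
      if (!snps$planted[i]) return(0)
      score_het_snp(pm, genome, snps[i], peaks = NULL, threshold = -Inf)$msd
    }, numeric(1))
    beta_true <- ifelse(snps$planted, plogis(spec$effect_slope * msd_true), 0.5)
    truth[, `:=`(msd_true = msd_true, beta_true = beta_true,
                 in_peak = peaks_contain(peaks, chrom, pos))]

    # allelic counts from the generative model
    rows <- vector("list", n_tot * spec$n_replicates)
    ri <- 0L
    for (i in seq_len(n_tot)) {
      for (r in seq_len(spec$n_replicates)) {
        n_reads <- max(1L, rpois(1L, spec$coverage_mean))
        cnt <- simulate_counts(beta_true[i], snps$raf[i], spec$rm_bias_true,
                               spec$dispersion_phi, n_reads)
        ri <- ri + 1L
        rows[[ri]] <- data.table::data.table(
          snp_id = snps$snp_id[i], replicate_id = sprintf("rep%d", r),
          ref_count = cnt[["ref_count"]], alt_count = cnt[["alt_count"]])
      }
    }
    counts <- data.table::rbindlist(rows)

    # motif reference file: planted motif (canonical for TF1) + decoys
    decoy1 <- motif("decoy_AT", {
      m <- matrix(0.02, 8L, 4L, dimnames = list(NULL, .BASES))
      m[, "A"] <- c(0.94, 0.02, 0.94, 0.02, 0.94, 0.02, 0.94, 0.02)
      m[, "T"] <- c(0.02, 0.94, 0.02, 0.94, 0.02, 0.94, 0.02, 0.94)
      m / rowSums(m)
    }, source = "JASPAR", tf = "TF_OTHER")
    decoy2 <- motif("decoy_GC", {
      m <- matrix(0.02, 8L, 4L, dimnames = list(NULL, .BASES))
      m[, "G"] <- c(0.94, 0.02, 0.94, 0.02, 0.94, 0.02, 0.94, 0.02)
      m[, "C"] <- c(0.02, 0.94, 0.02, 0.94, 0.02, 0.94, 0.02, 0.94)
      m / rowSums(m)
    }, source = "JASPAR", tf = "TF_OTHER2")
    motifs <- list(pm, decoy1, decoy2)

    reads <- NULL
    if (make_reads) {
      rlist <- vector("list", n_sites + 1L)
      for (si in seq_len(n_sites)) {
        s <- sites[si]
        nr <- spec$reads_per_site
        n_plus <- nr %/% 2L
        fp_plus <- s - sample(10:100, n_plus, replace = TRUE)
        fp_minus <- s + L - 1L + sample(10:100, nr - n_plus, replace = TRUE)
        rlist[[si]] <- data.table::data.table(
          chrom = "chr1",
          start = c(fp_plus - 1L, fp_minus - 50L),
          end = c(fp_plus + 49L, fp_minus),
          strand = rep(c("+", "-"), c(n_plus, nr - n_plus)))
      }
      bg_fp <- sample(seq(60L, glen - 60L), spec$n_background_reads, replace = TRUE)
      bg_str <- sample(c("+", "-"), spec$n_background_reads, replace = TRUE)
      rlist[[n_sites + 1L]] <- data.table::data.table(
        chrom = "chr1",
        start = ifelse(bg_str == "+", bg_fp - 1L, bg_fp - 50L),
        end = ifelse(bg_str == "+", bg_fp + 49L, bg_fp),
        strand = bg_str)
      reads <- data.table::rbindlist(rlist)
      reads <- reads[start >= 0L & end <= glen]
      data.table::setorder(reads, start)
    }

    bundle <- list(genome = genome, snps = snps, counts = counts,
                   peaks_df = peaks_df, peaks = peaks, truth = truth,
                   motifs = motifs, reads = reads, sites = sites, spec = spec)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        genome = file.path(dir, "genome.fa"),
        snps = file.path(dir, "snps.tsv"),
        counts = file.path(dir, "counts.tsv"),
        peaks = file.path(dir, "peaks.bed"),
        motifs = file.path(dir, "motifs.jaspar"),
        truth = file.path(dir, "truth_table.tsv"))
      writeLines(c(">chr1", genome[["chr1"]]), paths$genome)
      write_het_snps(snps[, !"planted"], paths$snps)
      data.table::fwrite(counts, paths$counts, sep = "\t")
      data.table::fwrite(peaks_df, paths$peaks, sep = "\t", col.names = FALSE)
      write_jaspar_pfm(motifs, paths$motifs)
      data.table::fwrite(truth, paths$truth, sep = "\t")
      if (!is.null(reads)) {
        paths$reads <- file.path(dir, "reads.bed")
        data.table::fwrite(reads[, .(chrom, start, end,
                                     name = ".", score = 0L, strand)],
                           paths$reads, sep = "\t", col.names = FALSE)
      }
      bundle$paths <- paths
    }
    bundle
  })
}
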