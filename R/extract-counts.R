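#' Extract per-SNP allelic read counts from indexed alignments
#'
#' Counts, per replicate, reads whose base at each heterozygous SNP equals
#' the REF or ALT allele. Duplicate-flagged reads are skipped when
#' `exclude_duplicates`, and bases matching neither allele are ignored.
#' SNPs lacking at least one read on *each* allele in the replicate-pooled
#' counts are dropped: sites covered on only one allele cannot inform
#' allelic imbalance.
#'
#' @param alignments named character vector of coordinate-sorted, indexed
#'   BAM paths; names are replicate identifiers.
#' @param het_snps SNP table from [read_het_snps()].
#' @param min_base_quality minimum base quality for a read base to count.
#' @param exclude_duplicates skip duplicate-flagged reads (default TRUE).
#' @return `data.table` with `snp_id`, `replicate_id`, `ref_count`,
#'   `alt_count` (zero-count replicate rows retained for surviving SNPs).
#' @export
extract_allelic_counts <- function(alignments, het_snps, min_base_quality = 10L,
                                   exclude_duplicates = TRUE) {
  snps <- data.table::as.data.table(het_snps)
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    names(alignments) <- paste0("rep", seq_along(alignments))
  if (nrow(snps) == 0L)
    return(data.table::data.table(snp_id = character(), replicate_id = character(),
                                  ref_count = integer(), alt_count = integer()))
  per_rep <- vector("list", length(alignments))
  for (r in seq_along(alignments)) {
    bam_path <- alignments[[r]]
    if (!file.exists(paste0(bam_path, ".bai")) &&
        !file.exists(sub("\\.bam$", ".bai", bam_path)))
      stop_fmt("asb_validation_error", "missing index for alignment file %s", bam_path)
    bf <- Rsamtools::BamFile(bam_path)
    hdr_chroms <- names(Rsamtools::scanBamHeader(bf)$targets)
    missing_chrom <- setdiff(unique(snps$chrom), hdr_chroms)
    if (length(missing_chrom))
      stop_fmt("asb_validation_error",
               "chromosomes in SNP table absent from %s: %s", bam_path,
               paste(missing_chrom, collapse = ", "))
    which_gr <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
    flag <- Rsamtools::scanBamFlag(
      isDuplicate = if (exclude_duplicates) FALSE else NA,
      isUnmappedQuery = FALSE)
    pp <- Rsamtools::PileupParam(max_depth = 100000L,
                                 min_base_quality = as.integer(min_base_quality),
                                 min_mapq = 0L, min_nucleotide_depth = 1L,
                                 distinguish_strands = FALSE,
                                 distinguish_nucleotides = TRUE,
                                 include_deletions = FALSE,
                                 include_insertions = FALSE)
    p <- Rsamtools::pileup(bf, scanBamParam = Rsamtools::ScanBamParam(
      which = which_gr, flag = flag), pileupParam = pp)
    p <- data.table::as.data.table(p)
    loc <- data.table::data.table(snp_id = snps$snp_id, chrom = snps$chrom,
                                  pos = snps$pos, ref = snps$ref, alt = snps$alt)
    if (nrow(p)) {
      p[, `:=`(chrom = as.character(seqnames), nucleotide = as.character(nucleotide))]
      m <- merge(loc, p[, .(chrom, pos, nucleotide, count)],
                 by = c("chrom", "pos"), allow.cartesian = TRUE)
      refs <- m[nucleotide == ref, .(ref_count = sum(count)), by = snp_id]
      alts <- m[nucleotide == alt, .(alt_count = sum(count)), by = snp_id]
    } else {
      refs <- data.table::data.table(snp_id = character(), ref_count = integer())
      alts <- data.table::data.table(snp_id = character(), alt_count = integer())
    }
    res <- merge(merge(loc[, .(snp_id)], refs, by = "snp_id", all.x = TRUE),
                 alts, by = "snp_id", all.x = TRUE)
    res[is.na(ref_count), ref_count := 0L]
    res[is.na(alt_count), alt_count := 0L]
    res[, replicate_id := names(alignments)[r]]
    per_rep[[r]] <- res
  }
  out <- data.table::rbindlist(per_rep, use.names = TRUE)
  pooled <- out[, .(ref = sum(ref_count), alt = sum(alt_count)), by = snp_id]
  keep <- pooled[ref >= 1L & alt >= 1L, snp_id]
  out <- out[snp_id %in% keep]
  data.table::setcolorder(out, c("snp_id", "replicate_id", "ref_count", "alt_count"))
  data.table::setorder(out, snp_id, replicate_id)[]
}
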