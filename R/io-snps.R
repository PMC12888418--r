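#' Read a heterozygous SNP table with genotype-quality filtering
#'
#' The canonical SNP table is tab-separated with header columns `snp_id`,
#' `chrom`, `pos` (1-based), `ref`, `alt`, `raf`, `genotype_quality`, and
#' optionally `maf`, `ancestral_allele`, `conservation` and `cell_line`.
#' Rows whose genotyping call rate is not strictly greater than
#' `min_quality` are removed on ingest (the published filter is a strict
#' "> 0.95 call rate").
#'
#' @param table path to a TSV file, or a data.frame with the same columns.
#' @param min_quality call-rate threshold; rows with
#'   `genotype_quality <= min_quality` are dropped.
#' @return a `data.table` of retained SNPs.
#' @export
read_het_snps <- function(table, min_quality = 0.95) {
  dt <- if (is.character(table)) {
    data.table::fread(table, sep = "\t", header = TRUE,
                      colClasses = list(character = "chrom"))
  } else data.table::as.data.table(table)
  req <- c("snp_id", "chrom", "pos", "ref", "alt", "raf", "genotype_quality")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop_fmt("asb_format_error", "SNP table missing columns: %s",
             paste(miss, collapse = ", "))
  if (nrow(dt) == 0L) return(dt)
  dt[, `:=`(pos = as.integer(pos), raf = as.numeric(raf),
            genotype_quality = as.numeric(genotype_quality),
            ref = toupper(ref), alt = toupper(alt),
            chrom = as.character(chrom))]
  if (any(dt$raf < 0 | dt$raf > 1))
    stop_fmt("asb_validation_error", "raf outside [0,1] for: %s",
             paste(head(dt$snp_id[dt$raf < 0 | dt$raf > 1], 5), collapse = ", "))
  if (any(dt$pos < 1L))
    stop_fmt("asb_validation_error", "pos < 1 for: %s",
             paste(head(dt$snp_id[dt$pos < 1L], 5), collapse = ", "))
  bad_allele <- !(dt$ref %in% .BASES) | !(dt$alt %in% .BASES) | dt$ref == dt$alt
  if (any(bad_allele))
    stop_fmt("asb_validation_error", "invalid or identical ref/alt alleles for: %s",
             paste(head(dt$snp_id[bad_allele], 5), collapse = ", "))
  if ("maf" %in% names(dt) && any(!is.na(dt$maf) & (dt$maf < 0 | dt$maf > 0.5)))
    stop_fmt("asb_validation_error", "maf outside [0, 0.5]")
  dt <- dt[dt$genotype_quality > min_quality]
  # duplicates within a cell line are an error; cross-cell-line repeats are fine
  key <- if ("cell_line" %in% names(dt)) paste(dt$cell_line, dt$snp_id) else dt$snp_id
  if (anyDuplicated(key))
    stop_fmt("asb_validation_error", "duplicated snp_id within a cell line: %s",
             paste(head(unique(key[duplicated(key)]), 5), collapse = ", "))
  dt[]
}

#' Write a heterozygous SNP table
#'
#' @param snps data.table/data.frame as returned by [read_het_snps()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_het_snps <- function(snps, path) {
  data.table::fwrite(snps, path, sep = "\t")
  invisible(path)
}

#' Read per-replicate allelic counts
#'
#' @param table TSV path or data.frame with columns `snp_id`,
#'   `replicate_id`, `ref_count`, `alt_count`.
#' @return a `data.table`; records with `ref_count + alt_count < 1` or
#'   negative counts are rejected.
#' @export
read_allelic_counts <- function(table) {
  dt <- if (is.character(table)) data.table::fread(table, sep = "\t", header = TRUE)
        else data.table::as.data.table(table)
  req <- c("snp_id", "replicate_id", "ref_count", "alt_count")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop_fmt("asb_format_error", "counts table missing columns: %s",
             paste(miss, collapse = ", "))
  if (nrow(dt) == 0L) return(dt)
  dt[, `:=`(ref_count = as.integer(ref_count), alt_count = as.integer(alt_count))]
  if (any(dt$ref_count < 0L | dt$alt_count < 0L))
    stop_fmt("asb_validation_error", "negative allelic counts")
  if (any(dt$ref_count + dt$alt_count < 1L))
    stop_fmt("asb_validation_error", "records with zero total reads")
  dt[]
}
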