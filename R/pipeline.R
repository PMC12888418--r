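#' Validate a pipeline run configuration
#'
#' A run configuration is a plain list (or a JSON file holding one) with
#' required entries `genome`, `snps`, `counts`, `peaks`, `jaspar`, `tf`,
#' `cell_line`, `output_dir`, and optional `reads` (BED6 for de novo motif
#' discovery), `seed`, and a `params` block overriding module defaults
#' (`model`, `fpr`, `flank`, `cluster_threshold`, `kmer`, `min_snps`).
#'
#' @param config list or path to a JSON config file.
#' @return the validated config list (with defaults filled in).
#' @export
load_run_config <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  req <- c("genome", "snps", "counts", "peaks", "jaspar", "tf", "cell_line",
           "output_dir")
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop_fmt("asb_validation_error", "config missing fields: %s",
             paste(miss, collapse = ", "))
  for (f in c("genome", "snps", "counts", "peaks", "jaspar", "reads")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p))
      stop_fmt("asb_validation_error", "config path '%s' does not exist: %s", f, p)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  defaults <- list(fpr = 0.05, flank = 25L, cluster_threshold = 0.7,
                   min_snps = 5L, fpr_draws = 100000L,
                   kmer = list(k = 8L, window_W = 200L, enrichment_min = 2.0,
                               min_occurrences = 50L, min_kmer_support = 10L),
                   model = list())
  config$params <- utils::modifyList(defaults, config$params %||% list())
  config
}

read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  setNames(as.character(ss), names(ss))
}

#' Run the full ASB + motif concordance pipeline
#'
#' Executes, in order: input loading, RM-bias estimation, per-SNP ASB
#' inference, optional de novo k-mer motif discovery with
#' clustering/classification against the JASPAR set (redundant motifs
#' excluded), FPR-calibrated SNP-motif scoring, motif-quality screening
#' (CAR-MSD Spearman concordance), High/Low/Unclassified ASB
#' classification, and summarisation. Each stage writes a TSV artifact in
#' `output_dir` and the manifest records input hashes, parameters and
#' per-stage row counts; rerunning an identical config reproduces
#' identical artifacts.
#'
#' @param config list or JSON path (see [load_run_config()]).
#' @return the manifest list, invisibly; artifacts are written to
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  config <- load_run_config(config)
  p <- config$params
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("asbmotif")),
                   seed = config$seed, params = p, stages = list(),
                   inputs = lapply(config[c("genome", "snps", "counts", "peaks",
                                            "jaspar", "reads")], function(f)
                     if (is.null(f)) NULL else unname(tools::md5sum(f))))
  stage <- function(name, n) {
    manifest$stages[[name]] <<- list(rows = n)
    message(sprintf("[%s] %s: %d rows", format(Sys.time(), "%H:%M:%S"), name, n))
  }

  genome <- read_genome_fasta(config$genome)
  snps <- read_het_snps(config$snps)
  counts <- read_allelic_counts(config$counts)
  peaks <- read_bed_peaks(config$peaks, tf = config$tf, cell_line = config$cell_line)
  jaspar <- read_jaspar_pfm(config$jaspar)
  stage("load_inputs", nrow(snps))

  b_hat <- suppressWarnings(estimate_rm_bias(counts))
  model_args <- utils::modifyList(list(rm_bias_b = b_hat, seed = config$seed),
                                  as.list(p$model))
  cfg <- do.call(model_config, model_args)
  calls <- infer_asb_table(counts, snps, cfg, tf = config$tf,
                           cell_line = config$cell_line)
  data.table::fwrite(calls, file.path(outdir, "asb_calls.tsv"), sep = "\t")
  stage("infer_asb", nrow(calls))

  # motif set: canonical JASPAR motifs for the target TF, plus (optionally)
  # de novo discovered motifs classified against the whole JASPAR set
  scoring_motifs <- list()
  for (m in jaspar) {
    if (identical(m$tf, config$tf)) {
      m$motif_class <- "canonical"
      scoring_motifs[[length(scoring_motifs) + 1L]] <- m
    }
  }
  discovered <- list()
  if (!is.null(config$reads)) {
    reads <- data.table::fread(config$reads, header = FALSE,
                               col.names = c("chrom", "start", "end", "name",
                                             "score", "strand")[1:6])
    kp <- p$kmer
    profiles <- build_kmer_profiles(reads, genome, k = kp$k,
                                    window_W = kp$window_W)
    selected <- select_binding_kmers(profiles, enrichment_min = kp$enrichment_min,
                                     min_occurrences = kp$min_occurrences)
    raw <- assemble_motifs(selected, min_kmer_support = kp$min_kmer_support,
                           name_prefix = basename(tools::file_path_sans_ext(config$reads)))
    trimmed <- lapply(raw, trim_motif_edges)
    clustered <- cluster_motifs(trimmed, threshold = p$cluster_threshold)
    for (m in clustered) {
      cl <- classify_nopeak_motif(m, jaspar, config$tf,
                                  threshold = p$cluster_threshold)
      if (cl == "redundant") next             # removed from further analysis
      m$motif_class <- cl
      discovered[[length(discovered) + 1L]] <- m
      scoring_motifs[[length(scoring_motifs) + 1L]] <- m
    }
    stage("motif_discovery", length(discovered))
  }
  if (length(scoring_motifs) == 0L)
    stop_fmt("asb_validation_error",
             "no scoring motifs: JASPAR file has no motif for TF '%s'", config$tf)

  thresholds <- vapply(scoring_motifs, function(m)
    fpr_threshold(m, fpr = p$fpr, window_len = 2L * p$flank + 1L, method = "mc",
                  n_draws = p$fpr_draws, seed = config$seed), numeric(1))
  score_rows <- list()
  for (mi in seq_along(scoring_motifs)) {
    m <- scoring_motifs[[mi]]
    for (i in seq_len(nrow(snps))) {
      r <- score_het_snp(m, genome, snps[i], peaks, flank = p$flank,
                         threshold = thresholds[mi])
      r$motif_class <- m$motif_class
      score_rows[[length(score_rows) + 1L]] <- r
    }
  }
  scores <- data.table::rbindlist(score_rows)
  data.table::fwrite(scores, file.path(outdir, "snp_motif_scores.tsv"), sep = "\t")
  stage("score_snps", nrow(scores))

  qualities <- motif_quality_table(scores, calls, min_snps = p$min_snps)
  data.table::fwrite(qualities, file.path(outdir, "motif_quality.tsv"), sep = "\t")
  stage("motif_quality", nrow(qualities))

  classified <- classify_asb_table(calls, scores, qualities)
  data.table::fwrite(classified, file.path(outdir, "classified_asb.tsv"), sep = "\t")
  stage("classify_asb", nrow(classified))

  summary <- summarize_distinct(classified)
  summary$distinct_by_quality <- as.list(summary$distinct_by_quality)
  summary$rows_by_quality <- as.list(summary$rows_by_quality)
  summary$rm_bias_b <- b_hat
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  stage("summarize", summary$n_distinct)

  manifest$complete <- TRUE
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
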