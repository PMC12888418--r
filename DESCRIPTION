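Package: asbmotif
Title: Allele-Specific Transcription Factor Binding with Motif Concordance
Version: 0.1.0
Authors@R: person("Maintainer", "Packages", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bayesian inference of allele-specific transcription factor
    binding (ASB) from ChIP-seq allelic read counts at heterozygous SNPs,
    with correction for copy-number imbalance (via the reference allele
    frequency) and reference-mapping bias under a beta-binomial model with
    highest-posterior-density calling. Downstream, the package maps SNPs to
    known (JASPAR) and de novo k-mer-discovered motifs, computes motif score
    differences, screens motifs by CAR-MSD Spearman concordance, classifies
    ASBs as High/Low/Unclassified quality, and builds MAF-matched empirical
    null comparator sets. Includes a deterministic synthetic-fixture
    generator with planted motif-disrupting ASBs so the full pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
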