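#' Configuration for the synthetic single-cell allele-data generator
#'
#' Bundles and validates every knob of \code{\link{simulate_dataset}}.  The
#' defaults describe a small but structurally faithful 10x-style 3' scRNA-seq
#' experiment: 14 nt cell barcodes, 10 nt UMIs, 150 nt single-end reads, and
#' per-(cell, SNV) molecule depths drawn from a configurable model.
#'
#' @param seed integer seed; identical seeds give byte-identical output files.
#' @param n_cells number of cells (droplet barcodes).
#' @param n_genes number of genes; one toy contig is emitted per gene.
#' @param snvs_per_gene heterozygous SNV loci placed on each gene contig.
#' @param barcode_length cell-barcode length in nt (10x v2 uses 14... here a
#'   default, not a constraint).
#' @param umi_length UMI length in nt.
#' @param read_length single-end read length in nt.
#' @param depth_model per-(cell, SNV) unique-molecule depth model; one of
#'   \code{list(kind = "fixed", n = )}, \code{list(kind = "poisson", lambda = )}
#'   or \code{list(kind = "nb", mean = , dispersion = )} (negative binomial
#'   with \code{size = dispersion}).
#' @param class_fractions named proportions over the allelic classes
#'   \code{symmetric}, \code{skewed}, \code{RME}, \code{strict_mono}; must sum
#'   to 1.  Omitted classes default to 0.
#' @param skew_p allele fraction of the favoured allele at skewed loci; the
#'   favoured side (ref or alt) is a fair coin per locus.
#' @param overdispersion beta-binomial concentration for symmetric loci;
#'   \code{Inf} (default) is a pure binomial at p = 0.5.
#' @param pcr_duplication_rate mean number of extra PCR copies per unique
#'   molecule (Poisson); each copy shares the molecule's (CB, UB) and position.
#' @param fraction_intronic_snvs proportion of SNVs annotated as intronic.
#' @param intron_depth_scale multiplier (usually < 1) applied to the depth
#'   model at intronic SNVs, emulating lower intronic read counts.
#' @param base_error_rate per-record probability that the emitted base at the
#'   SNV position is replaced by a uniformly chosen different base.
#' @param wasp_fail_rate proportion (relative to the number of true molecules)
#'   of extra reads emitted with alignment tag \code{vW:i:2}, i.e. reads a
#'   WASP-style allele-mapping-bias filter would remove.  They carry fresh
#'   UMIs so honouring the tag reproduces the truth table exactly.
#' @param n_bad_cells_low_genes cells engineered to fail QC on detected genes.
#' @param n_bad_cells_high_mito cells engineered to fail QC on mitochondrial
#'   fraction (disjoint from the low-gene set).
#' @param n_matrix_genes total non-mitochondrial genes in the emitted
#'   gene-by-cell matrix (must exceed \code{qc_target_genes}).
#' @param n_mito_genes mitochondrial genes (named with prefix \code{MT-}).
#' @param qc_target_genes detected-gene count that "good" cells are simulated
#'   above (the QC threshold the matrix is engineered around).
#' @param qc_target_pct_mito mitochondrial percentage good and low-gene cells
#'   are simulated near (safely below a 6\% QC threshold).
#' @param qc_fail_pct_mito mitochondrial percentage high-mito cells are
#'   simulated near (safely above the threshold).
#' @param vcf_fail named integer vector \code{c(qual=, mq=, qd=, fs=)}: how
#'   many SNVs get VCF fields engineered to fail each variant-quality gate.
#'
#' @return an object of class \code{scvaf_sim_config} (a validated list).
#' @seealso \code{\link{simulate_dataset}}
#' @export
sim_config <- function(seed = 1L,
                       n_cells = 100L,
                       n_genes = 10L,
                       snvs_per_gene = 2L,
                       barcode_length = 14L,
                       umi_length = 10L,
                       read_length = 150L,
                       depth_model = list(kind = "fixed", n = 5L),
                       class_fractions = c(symmetric = 1),
                       skew_p = 0.9,
                       overdispersion = Inf,
                       pcr_duplication_rate = 0,
                       fraction_intronic_snvs = 0,
                       intron_depth_scale = 1,
                       base_error_rate = 0,
                       wasp_fail_rate = 0,
                       n_bad_cells_low_genes = 0L,
                       n_bad_cells_high_mito = 0L,
                       n_matrix_genes = 3500L,
                       n_mito_genes = 13L,
                       qc_target_genes = 3000L,
                       qc_target_pct_mito = 2,
                       qc_fail_pct_mito = 12,
                       vcf_fail = c(qual = 0L, mq = 0L, qd = 0L, fs = 0L)) {
  cfg <- as.list(environment())
  # JSON configs arrive as named lists; flatten scalar-list fields
  if (is.list(class_fractions)) class_fractions <- unlist(class_fractions)
  if (is.list(cfg$vcf_fail)) cfg$vcf_fail <- unlist(cfg$vcf_fail)
  classes <- c("symmetric", "skewed", "RME", "strict_mono")
  cf <- setNames(numeric(4), classes)
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% classes))
    .stop_config("class_fractions must be named with a subset of: ",
                 paste(classes, collapse = ", "))
  cf[names(class_fractions)] <- class_fractions
  if (abs(sum(cf) - 1) > 1e-8)
    .stop_config("class_fractions must sum to 1")
  cfg$class_fractions <- cf

  for (f in c("n_cells", "n_genes", "snvs_per_gene"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1)
      .stop_config(f, " must be a positive integer (degenerate config rejected)")
  for (f in c("barcode_length", "umi_length", "read_length"))
    if (cfg[[f]] < 1) .stop_config(f, " must be >= 1")
  for (f in c("pcr_duplication_rate", "fraction_intronic_snvs",
              "intron_depth_scale", "base_error_rate", "wasp_fail_rate",
              "n_bad_cells_low_genes", "n_bad_cells_high_mito"))
    if (cfg[[f]] < 0) .stop_config(f, " must be >= 0")
  if (skew_p <= 0 || skew_p >= 1) .stop_config("skew_p must be in (0, 1)")
  if (cfg$n_bad_cells_low_genes + cfg$n_bad_cells_high_mito > cfg$n_cells)
    .stop_config("more engineered bad cells than cells")
  if (cfg$n_matrix_genes <= cfg$qc_target_genes + 60)
    .stop_config("n_matrix_genes must exceed qc_target_genes with headroom")

  dm <- cfg$depth_model
  ok <- is.list(dm) && !is.null(dm$kind) &&
    dm$kind %in% c("fixed", "poisson", "nb") &&
    switch(dm$kind,
           fixed   = !is.null(dm$n) && dm$n >= 0,
           poisson = !is.null(dm$lambda) && dm$lambda >= 0,
           nb      = !is.null(dm$mean) && !is.null(dm$dispersion) &&
                     dm$mean >= 0 && dm$dispersion > 0)
  if (!ok)
    .stop_config("depth_model must be fixed(n)/poisson(lambda)/nb(mean, dispersion)")

  vf <- setNames(integer(4), c("qual", "mq", "qd", "fs"))
  vf[names(cfg$vcf_fail)] <- as.integer(cfg$vcf_fail)
  if (sum(vf) > cfg$n_genes * cfg$snvs_per_gene)
    .stop_config("vcf_fail assigns more failures than SNVs")
  cfg$vcf_fail <- vf

  cfg$seed <- as.integer(seed)
  for (f in c("n_cells", "n_genes", "snvs_per_gene", "barcode_length",
              "umi_length", "read_length", "n_bad_cells_low_genes",
              "n_bad_cells_high_mito", "n_matrix_genes", "n_mito_genes",
              "qc_target_genes"))
    cfg[[f]] <- as.integer(cfg[[f]])
  structure(cfg, class = "scvaf_sim_config")
}

#' @export
print.scvaf_sim_config <- function(x, ...) {
  cat("scvaf simulation config:\n")
  cat(sprintf("  %d cells x %d genes x %d SNVs/gene, seed %d\n",
              x$n_cells, x$n_genes, x$snvs_per_gene, x$seed))
  cat("  depth model:", x$depth_model$kind, "| class fractions:",
      paste(sprintf("%s=%.2f", names(x$class_fractions), x$class_fractions),
            collapse = " "), "\n")
  invisible(x)
}
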