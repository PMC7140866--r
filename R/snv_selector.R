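# Heterozygous-SNV selection: pooled-count rule + variant-quality gates +
# annotation exclusion, with first-failing-rule audit.

#' Configuration of the heterozygosity/quality filter
#'
#' Defaults mirror the selection used for pooled 10x alignments: at least 50
#' deduplicated reads supporting each allele in the pooled counts, QUAL > 100,
#' MQ > 60, QD > 2, FS exactly 0, and exclusion of repetitive or intergenic
#' loci.  "At least 50" is inclusive (>= 50); QUAL/MQ/QD are strict
#' inequalities; FS equality is tested within \code{fs_tol}.
#'
#' @param min_reads_per_allele pooled unique-molecule minimum per allele.
#' @param min_qual,min_mq,min_qd strict lower bounds on QUAL, MQ, QD.
#' @param max_fs required FS value (equality); \code{fs_tol} its tolerance.
#' @param fs_tol numeric tolerance for the FS equality.
#' @param excluded_categories annotation categories removed outright.
#' @param skip_count_rule bypass the pooled-count heterozygosity rule, for
#'   workflows where heterozygosity comes from an external genotype VCF.
#' @return object of class \code{scvaf_het_filter_config}.
#' @export
het_filter_config <- function(min_reads_per_allele = 50L,
                              min_qual = 100,
                              min_mq = 60,
                              min_qd = 2,
                              max_fs = 0,
                              fs_tol = 1e-9,
                              excluded_categories = c("repetitive",
                                                      "intergenic"),
                              skip_count_rule = FALSE) {
  cfg <- as.list(environment())
  for (f in c("min_reads_per_allele", "min_qual", "min_mq", "min_qd",
              "max_fs", "fs_tol"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      .stop_config(f, " must be a non-negative number")
  structure(cfg, class = "scvaf_het_filter_config")
}

#' Select high-confidence heterozygous SNVs
#'
#' Applies, in a fixed order, the pooled-count heterozygosity rule, the
#' QUAL/MQ/QD/FS variant-quality gates and the annotation-category exclusion.
#' Each rejected SNV is labelled with the first failing rule
#' (\code{counts}, \code{qual}, \code{mq}, \code{qd}, \code{fs},
#' \code{annotation}); an SNV whose required quality field is missing (NA) is
#' rejected with reason \code{missing_field} at that gate, never silently
#' passed.  SNVs absent from the pooled table have zero pooled counts.
#'
#' @param snvs SNV table (see \code{\link{read_snv_vcf}}); columns
#'   \code{snv_id}, \code{qual}, \code{mq}, \code{qd}, \code{fs} and
#'   optionally \code{category}.
#' @param pooled pooled counts from \code{\link{pool_counts}}.
#' @param cfg a \code{\link{het_filter_config}}.
#' @return list with \code{retained} (the surviving rows of \code{snvs}, in
#'   input order) and \code{audit} (snv_id, retained, reason; reason is
#'   \code{"pass"} for survivors).
#' @export
select_het_snvs <- function(snvs, pooled, cfg = het_filter_config()) {
  stopifnot(inherits(cfg, "scvaf_het_filter_config"))
  snvs <- data.table::as.data.table(snvs)
  pooled <- data.table::as.data.table(pooled)
  if (!"category" %in% names(snvs)) snvs[, category := NA_character_]

  x <- data.table::copy(snvs)
  x[, `:=`(N_ref = 0L, N_var = 0L)]
  if (nrow(pooled))
    x[pooled, on = "snv_id", `:=`(N_ref = i.N_ref, N_var = i.N_var)]

  n <- nrow(x)
  reason <- rep(NA_character_, n)
  gate <- function(fail, why) {
    hit <- is.na(reason) & fail
    reason[hit] <<- why
  }
  # fixed evaluation order: counts, qual, mq, qd, fs, annotation
  if (!cfg$skip_count_rule)
    gate(x$N_ref < cfg$min_reads_per_allele |
           x$N_var < cfg$min_reads_per_allele, "counts")
  gate(is.na(x$qual), "missing_field"); gate(x$qual <= cfg$min_qual, "qual")
  gate(is.na(x$mq), "missing_field");   gate(x$mq <= cfg$min_mq, "mq")
  gate(is.na(x$qd), "missing_field");   gate(x$qd <= cfg$min_qd, "qd")
  gate(is.na(x$fs), "missing_field")
  gate(abs(x$fs - cfg$max_fs) > cfg$fs_tol, "fs")
  gate(!is.na(x$category) & x$category %in% cfg$excluded_categories,
       "annotation")
  reason[is.na(reason)] <- "pass"

  audit <- data.table::data.table(snv_id = x$snv_id,
                                  retained = reason == "pass",
                                  reason = reason)
  list(retained = snvs[reason == "pass"], audit = audit)
}
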