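# Pipeline orchestration: qc -> count -> select -> (restrict) -> vaf -> report.
#
# Every stage is a pure function of its declared inputs; with a fixed config
# and seed, the whole output tree is byte-identical across runs (manifest
# timestamps are off by default for exactly this reason).

.default_config <- function() {
  list(
    seed = 1L,
    simulate = NULL,   # sim_config args; NULL means inputs are supplied
    inputs = list(alignment = NULL, vcf = NULL, annotation = NULL,
                  matrix_dir = NULL),
    qc = list(min_genes = 3000L, max_pct_mito = 6.0, mito_prefix = "MT-"),
    count = list(min_base_qual = 20L, min_map_qual = 30L,
                 honor_wasp_tag = TRUE),
    select = list(min_reads_per_allele = 50L, min_qual = 100, min_mq = 60,
                  min_qd = 2, max_fs = 0, fs_tol = 1e-9,
                  excluded_categories = c("repetitive", "intergenic"),
                  skip_count_rule = FALSE),
    vaf = list(lower = 0.2, upper = 0.8, min_cells_stats = 10L,
               min_cells_pattern = 50L, rme_max_biallelic_frac = 0.05,
               skew_min_one_allele_frac = 0.10,
               skew_max_biallelic_frac = 0.80, minr_grid = c(3L, 5L, 10L)),
    manifest_timestamps = FALSE)
}

.merge_config <- function(user, defaults = .default_config()) {
  if (is.null(user)) return(defaults)
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(defaults[[k]]) &&
        !is.null(names(defaults[[k]])))
      defaults[[k]] <- .merge_config(user[[k]], defaults[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Load (and complete) a pipeline configuration
#'
#' Reads a JSON config with one section per stage (\code{simulate},
#' \code{qc}, \code{count}, \code{select}, \code{vaf}) and fills every
#' missing key with the package default, so a config only states what it
#' overrides.
#'
#' @param path JSON file, or a named list already in memory, or NULL for the
#'   full defaults.
#' @return the completed configuration list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL
  else if (is.character(path)) {
    if (!file.exists(path)) .stop_config("config file not found: ", path)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (is.list(path)) path
  else .stop_config("config must be a JSON path or a list")
  .merge_config(user)
}

.manifest <- function(out_dir, config, inputs, stage_rows, seed,
                      timestamps = FALSE) {
  files <- unlist(inputs, use.names = TRUE)
  files <- files[!is.na(files) & file.exists(files) & !dir.exists(files)]
  checks <- tools::md5sum(files)
  names(checks) <- basename(files)  # keys independent of the run directory
  man <- list(
    tool = "scvaf",
    version = as.character(utils::packageVersion("scvaf")),
    seed = seed,
    config = config,
    input_checksums = as.list(checks),
    stage_rows = stage_rows)
  if (timestamps) man$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(man)
}

#' Run the full single-cell VAF pipeline
#'
#' Executes, in order: synthetic-data generation (when the config carries a
#' \code{simulate} section), cell QC, whitelist-restricted allele counting,
#' pooled heterozygosity selection, restriction of the counts to the selected
#' SNVs, VAF_RNA estimation and allelic-pattern analysis over the minR grid,
#' and report rendering.  All stage outputs land under \code{out} as plain
#' TSV/JSON, plus a machine-readable run manifest.
#'
#' The second counting pass of the workflow (counting restricted to selected
#' SNVs and passing cells) is realised by subsetting the whitelist-restricted
#' counts table to the selected loci: counting is independent per locus and
#' per cell, so the subset equals a re-pileup over the restricted inputs.
#'
#' @param config JSON path or list, see \code{\link{load_config}}.
#' @param out output directory (defaults to \code{config$out}).
#' @return invisibly, a list with every stage product (truth, qc, counts,
#'   pooled, selection, estimates, summaries, gene_table, intronic,
#'   histograms, tables, manifest) and \code{out}.
#' @export
run_pipeline <- function(config = NULL, out = NULL) {
  cfg <- load_config(config)
  out <- out %||% cfg$out
  if (is.null(out)) .stop_config("no output directory given")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)

  truth <- NULL
  inputs <- cfg$inputs
  if (!is.null(cfg$simulate)) {
    .msg("stage simulate")
    sim_args <- cfg$simulate
    sim_args$seed <- NULL
    sc <- do.call(sim_config, c(sim_args, list(seed = seed)))
    truth <- simulate_dataset(sc, file.path(out, "sim"))
    inputs <- list(alignment = truth$paths$alignment,
                   vcf = truth$paths$vcf,
                   annotation = truth$paths$annotation,
                   matrix_dir = truth$paths$matrix_dir)
  }
  for (f in c("alignment", "vcf", "annotation", "matrix_dir"))
    if (is.null(inputs[[f]]) || !file.exists(inputs[[f]]))
      .stop_config("missing input: ", f)

  .msg("stage qc")
  mat <- read_counts_mtx(inputs$matrix_dir)
  qc <- qc_cells(mat, mito_prefix = cfg$qc$mito_prefix,
                 min_genes = cfg$qc$min_genes,
                 max_pct_mito = cfg$qc$max_pct_mito)
  .write_tsv(qc, file.path(out, "cells.tsv"))
  whitelist <- qc$barcode[qc$pass_qc]
  writeLines(whitelist, file.path(out, "whitelist.txt"))
  .msg(sprintf("  %d/%d cells pass QC", length(whitelist), nrow(qc)))

  .msg("stage count")
  snvs <- read_snv_vcf(inputs$vcf, annotation = inputs$annotation)
  counts <- count_alleles(inputs$alignment, snvs,
                          barcode_whitelist = whitelist,
                          min_base_qual = cfg$count$min_base_qual,
                          min_map_qual = cfg$count$min_map_qual,
                          honor_wasp_tag = isTRUE(cfg$count$honor_wasp_tag))
  .write_tsv(counts, file.path(out, "counts.tsv"))

  .msg("stage select-snvs")
  pooled <- pool_counts(counts)
  .write_tsv(pooled, file.path(out, "pooled.tsv"))
  hcfg <- do.call(het_filter_config, cfg$select)
  sel <- select_het_snvs(snvs, pooled, hcfg)
  .write_tsv(sel$audit, file.path(out, "snv_filter_audit.tsv"))
  write_snv_vcf(sel$retained, file.path(out, "selected.vcf"))
  .msg(sprintf("  %d/%d SNVs retained", nrow(sel$retained), nrow(snvs)))

  # restricted counting pass: selected SNVs x passing cells
  counts_sel <- counts[snv_id %in% sel$retained$snv_id]
  .write_tsv(counts_sel, file.path(out, "counts_selected.tsv"))

  .msg("stage vaf")
  ccfg <- do.call(classification_config, cfg$vaf)
  estimates <- list(); summaries <- list(); histograms <- list()
  intronic <- list()
  for (mr in ccfg$minr_grid) {
    key <- sprintf("minR%d", mr)
    est <- estimate_vaf(counts_sel, mr)
    .write_tsv(est, file.path(out, sprintf("vaf_%s.tsv", key)))
    sm <- summarize_snv(est, ccfg)
    hist <- vaf_histogram(est)
    .write_tsv(hist, file.path(out, sprintf("histogram_%s.tsv", key)))
    ci <- compare_intronic(est, snvs[, .(snv_id, category)], ccfg)
    estimates[[key]] <- est; summaries[[key]] <- sm
    histograms[[key]] <- hist; intronic[[key]] <- ci
  }
  summary_all <- data.table::rbindlist(summaries)
  .write_tsv(summary_all, file.path(out, "snv_summary.tsv"))
  gene_table <- aggregate_gene(summary_all, inputs$annotation)
  .write_tsv(gene_table, file.path(out, "gene_table.tsv"))
  jsonlite::write_json(
    lapply(intronic, function(ci)
      list(applicable = ci$applicable,
           table = if (ci$applicable) as.vector(t(ci$table)) else NULL,
           statistic = ci$statistic, p_value = ci$p_value,
           prop_biallelic = as.list(ci$prop_biallelic))),
    file.path(out, "intronic_chisq.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")

  .msg("stage report")
  tables <- render_summary_tables(list(qc = qc, snvs = snvs, selection = sel,
                                       counts = counts_sel,
                                       estimates = estimates,
                                       summaries = summaries))
  .write_tsv(tables$table1, file.path(out, "table1.tsv"))
  .write_tsv(tables$table2, file.path(out, "table2.tsv"))

  stage_rows <- list(
    cells_total = nrow(qc), cells_pass = length(whitelist),
    snvs_candidate = nrow(snvs), snvs_selected = nrow(sel$retained),
    count_rows = nrow(counts), count_rows_selected = nrow(counts_sel),
    estimates = lapply(estimates, nrow),
    summaries = lapply(summaries, nrow))
  man <- .manifest(out, cfg, inputs, stage_rows, seed,
                   timestamps = isTRUE(cfg$manifest_timestamps))

  invisible(list(out = out, truth = truth, qc = qc, snvs = snvs,
                 counts = counts, counts_selected = counts_sel,
                 pooled = pooled, selection = sel, estimates = estimates,
                 summaries = summaries, gene_table = gene_table,
                 intronic = intronic, histograms = histograms,
                 tables = tables, manifest = man))
}

#' Render per-stage count and allelic-percentage tables
#'
#' Builds two report tables from pipeline products: a per-stage summary
#' (cells and SNVs surviving each stage, SNVs with at least 10 cells per
#' minR) and a per-minR allelic table giving the percentage of strictly
#' monoallelic, predominantly monoallelic and bi-allelic per-cell VAF_RNA
#' measurements (one decimal; predominant + bi-allelic = 100 by
#' construction).
#'
#' @param products list with elements \code{qc}, \code{snvs},
#'   \code{selection}, \code{estimates} (list per minR), \code{summaries}
#'   (list per minR).
#' @return list(table1, table2) of data.tables.
#' @export
render_summary_tables <- function(products) {
  est_list <- products$estimates
  sum_list <- products$summaries

  t1 <- data.table::data.table(
    metric = c("cells_total", "cells_pass_qc", "snvs_candidate",
               "snvs_selected",
               sprintf("snvs_min10cells_%s", names(sum_list))),
    value = c(nrow(products$qc), sum(products$qc$pass_qc),
              nrow(products$snvs), nrow(products$selection$retained),
              vapply(sum_list, function(s)
                if (nrow(s)) sum(s$n_cells >= 10L) else 0L, numeric(1))))

  t2 <- data.table::rbindlist(lapply(names(est_list), function(key) {
    est <- est_list[[key]]
    if (nrow(est) == 0L)
      return(data.table::data.table(
        minR = est_list[[key]]$minR[0], n_estimates = integer(0),
        pct_strict_mono = numeric(0), pct_predom_mono = numeric(0),
        pct_biallelic = numeric(0)))
    fr <- allelic_fractions(est)
    data.table::data.table(
      minR = est$minR[1L], n_estimates = nrow(est),
      pct_strict_mono = round(100 * fr["strict"], 1),
      pct_predom_mono = round(100 * fr["predom"], 1),
      pct_biallelic = round(100 * fr["biallelic"], 1))
  }))
  list(table1 = t1, table2 = t2)
}

#' Dataset-wide allelic fractions of per-cell VAF_RNA measurements
#'
#' Fractions of all estimates that are strictly monoallelic (VAF exactly 0 or
#' 1), predominantly monoallelic (VAF <= lower or >= upper) and bi-allelic
#' (in between); the last two partition the measurements.
#'
#' @param estimates output of \code{\link{estimate_vaf}}.
#' @param lower,upper bi-allelic interval bounds.
#' @return named numeric vector (strict, predom, biallelic).
#' @export
allelic_fractions <- function(estimates, lower = 0.2, upper = 0.8) {
  est <- data.table::as.data.table(estimates)
  if (nrow(est) == 0L)
    return(c(strict = NA_real_, predom = NA_real_, biallelic = NA_real_))
  strict <- est$n_var == 0L | est$n_ref == 0L
  predom <- est$vaf <= lower | est$vaf >= upper
  c(strict = mean(strict), predom = mean(predom),
    biallelic = mean(!predom))
}
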