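# VAF_RNA estimation and allelic-pattern classification.
#
# VAF_RNA = n_var / (n_var + n_ref); n_other never enters the denominator.
# Strict monoallelic status (VAF exactly 0 or 1) is decided on the integer
# counts (n_var == 0 or n_ref == 0), not by floating-point comparison.

#' Classification configuration for allelic patterns
#'
#' Thresholds for per-cell and per-SNV allelic calls.  A per-cell estimate is
#' bi-allelic on the open interval \code{lower < VAF < upper} and
#' predominantly monoallelic otherwise (boundaries count as monoallelic);
#' strictly monoallelic estimates (VAF exactly 0 or 1) are a subset of the
#' predominantly monoallelic ones.  Per SNV, random monoallelic expression
#' (RME) is called when fewer than \code{rme_max_biallelic_frac} of the cells
#' are bi-allelic; otherwise a skewed pattern is called when under
#' \code{skew_min_one_allele_frac} of the cells express one of the alleles
#' (VAF beyond one boundary) and fewer than \code{skew_max_biallelic_frac}
#' are bi-allelic; otherwise the SNV is bi-allelic.
#'
#' @param lower,upper bi-allelic interval bounds (open), defaults 0.2 / 0.8.
#' @param min_cells_stats minimum cells for per-SNV statistics (default 10).
#' @param min_cells_pattern minimum cells for a pattern call (default 50).
#' @param rme_max_biallelic_frac RME rule: bi-allelic cell fraction < this
#'   (default 0.05).
#' @param skew_min_one_allele_frac skew rule: the rarer allele is expressed
#'   (alone) by fewer than this fraction of cells (default 0.10).
#' @param skew_max_biallelic_frac skew rule: bi-allelic cell fraction below
#'   this (default 0.80).
#' @param minr_grid minR thresholds analysed in a full run (default 3, 5, 10).
#' @return object of class \code{scvaf_classification_config}.
#' @export
classification_config <- function(lower = 0.2, upper = 0.8,
                                  min_cells_stats = 10L,
                                  min_cells_pattern = 50L,
                                  rme_max_biallelic_frac = 0.05,
                                  skew_min_one_allele_frac = 0.10,
                                  skew_max_biallelic_frac = 0.80,
                                  minr_grid = c(3L, 5L, 10L)) {
  cfg <- as.list(environment())
  if (!(lower > 0 && lower < upper && upper < 1))
    .stop_config("need 0 < lower < upper < 1")
  for (f in c("rme_max_biallelic_frac", "skew_min_one_allele_frac",
              "skew_max_biallelic_frac"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) .stop_config(f, " must be in [0, 1]")
  if (any(minr_grid < 1)) .stop_config("minR thresholds must be >= 1")
  cfg$min_cells_stats <- as.integer(min_cells_stats)
  cfg$min_cells_pattern <- as.integer(min_cells_pattern)
  cfg$minr_grid <- as.integer(sort(unique(minr_grid)))
  structure(cfg, class = "scvaf_classification_config")
}

#' Per-cell VAF_RNA estimates at a read-depth threshold
#'
#' Computes VAF_RNA = n_var / (n_var + n_ref) for every (cell, SNV) whose
#' informative depth n_ref + n_var reaches \code{minR}; pairs below the
#' threshold are omitted, and \code{n_other} molecules are excluded from the
#' denominator.
#'
#' @param counts allele-count table (cell_barcode, snv_id, n_ref, n_var).
#' @param minR minimum unique informative molecules; must be >= 1.
#' @return data.table (cell_barcode, snv_id, n_ref, n_var, vaf,
#'   depth_informative, minR).
#' @export
estimate_vaf <- function(counts, minR) {
  if (!is.numeric(minR) || length(minR) != 1L || minR < 1)
    .stop_config("minR must be a single integer >= 1")
  minR <- as.integer(minR)
  counts <- .check_counts(counts)
  est <- counts[n_ref + n_var >= minR,
                .(cell_barcode, snv_id, n_ref, n_var)]
  est[, depth_informative := n_ref + n_var]
  est[, vaf := n_var / depth_informative]
  est[, minR := minR]
  est[]
}

#' Cross-cell summary statistics per SNV
#'
#' For each SNV at a single minR: number of cells, mean and median VAF_RNA,
#' and the fractions of cells that are strictly monoallelic (VAF exactly 0 or
#' 1), predominantly monoallelic (VAF <= lower or >= upper, inclusive of
#' strict), and bi-allelic (lower < VAF < upper).  The bi-allelic and
#' predominantly monoallelic fractions partition the cells, so they sum to 1.
#' SNVs observed in fewer than \code{min_cells_stats} cells are emitted with
#' pattern \code{insufficient_cells} and NA statistics.  SNVs with enough
#' cells for statistics but fewer than \code{min_cells_pattern} also keep
#' pattern \code{insufficient_cells}; see \code{\link{classify_pattern}}.
#'
#' @param estimates output of \code{\link{estimate_vaf}} (one minR per call).
#' @param cfg a \code{\link{classification_config}}.
#' @return data.table (snv_id, minR, n_cells, mean_vaf, median_vaf,
#'   frac_strict_mono, frac_predom_mono, frac_biallelic, frac_low, frac_high,
#'   pattern).
#' @export
summarize_snv <- function(estimates, cfg = classification_config()) {
  stopifnot(inherits(cfg, "scvaf_classification_config"))
  est <- data.table::as.data.table(estimates)
  if (nrow(est) == 0L)
    return(data.table::data.table(
      snv_id = character(0), minR = integer(0), n_cells = integer(0),
      mean_vaf = numeric(0), median_vaf = numeric(0),
      frac_strict_mono = numeric(0), frac_predom_mono = numeric(0),
      frac_biallelic = numeric(0), frac_low = numeric(0),
      frac_high = numeric(0), pattern = character(0)))
  mr <- unique(est$minR)
  if (length(mr) != 1L)
    .stop_data("summarize_snv expects estimates at a single minR")

  s <- est[, {
    strict <- n_var == 0L | n_ref == 0L
    low <- vaf <= cfg$lower
    high <- vaf >= cfg$upper
    bi <- !(low | high)
    .(n_cells = .N,
      mean_vaf = mean(vaf), median_vaf = stats::median(vaf),
      frac_strict_mono = sum(strict) / .N,
      frac_predom_mono = sum(low | high) / .N,
      frac_biallelic = sum(bi) / .N,
      frac_low = sum(low) / .N, frac_high = sum(high) / .N)
  }, by = snv_id]
  too_few <- s$n_cells < cfg$min_cells_stats
  for (col in c("mean_vaf", "median_vaf", "frac_strict_mono",
                "frac_predom_mono", "frac_biallelic", "frac_low",
                "frac_high"))
    s[too_few, (col) := NA_real_]
  s[, minR := mr]
  s[, pattern := classify_pattern(s, cfg)]
  data.table::setcolorder(s, c("snv_id", "minR", "n_cells"))
  data.table::setorderv(s, "snv_id")
  s[]
}

#' Allelic-pattern label per SNV
#'
#' Applies the RME / skewed / bi-allelic decision rules to SNV summaries.
#' The RME rule takes precedence: RME iff the bi-allelic cell fraction is
#' below \code{rme_max_biallelic_frac}; otherwise skewed iff the rarer
#' exclusively-expressed allele is seen in fewer than
#' \code{skew_min_one_allele_frac} of cells and the bi-allelic fraction is
#' below \code{skew_max_biallelic_frac}; otherwise bi-allelic.  SNVs with
#' fewer than \code{min_cells_pattern} cells (or NA fractions) get
#' \code{insufficient_cells}.
#'
#' @param summary SNV summary table (see \code{\link{summarize_snv}}) with
#'   columns n_cells, frac_biallelic, frac_low, frac_high.
#' @param cfg a \code{\link{classification_config}}.
#' @return character vector of labels, one per row: \code{"RME"},
#'   \code{"skewed"}, \code{"biallelic"} or \code{"insufficient_cells"}.
#' @export
classify_pattern <- function(summary, cfg = classification_config()) {
  stopifnot(inherits(cfg, "scvaf_classification_config"))
  s <- data.table::as.data.table(summary)
  out <- rep("insufficient_cells", nrow(s))
  ok <- s$n_cells >= cfg$min_cells_pattern & !is.na(s$frac_biallelic)
  rme <- ok & s$frac_biallelic < cfg$rme_max_biallelic_frac
  skew <- ok & !rme &
    pmin(s$frac_low, s$frac_high) < cfg$skew_min_one_allele_frac &
    s$frac_biallelic < cfg$skew_max_biallelic_frac
  out[rme] <- "RME"
  out[skew] <- "skewed"
  out[ok & !rme & !skew] <- "biallelic"
  out
}

#' Gene-level aggregation of SNV summaries
#'
#' Joins gene and functional category onto the SNV summaries and aggregates
#' per gene and minR: member SNVs split into intronic and non-intronic
#' groups with per-group mean bi-allelic cell fraction, a concordance score
#' (maximum pairwise absolute difference of the bi-allelic fractions among
#' member SNVs; 0 for a singleton), and a gene-level pattern obtained by
#' majority vote over the member patterns (ties give \code{"discordant"};
#' members labelled \code{insufficient_cells} do not vote, and a gene with no
#' voting member is \code{insufficient_cells}).
#'
#' @param summaries SNV summary table, possibly several minR values stacked.
#' @param annotation table (or TSV path) with snv_id, gene, category.
#' @return data.table per (gene, minR): n_snvs, n_intronic, n_non_intronic,
#'   mean_frac_biallelic, mean_frac_biallelic_intronic,
#'   mean_frac_biallelic_non_intronic, concordance, pattern.
#' @export
aggregate_gene <- function(summaries, annotation) {
  s <- data.table::as.data.table(summaries)
  ann <- if (is.character(annotation)) data.table::fread(annotation)
         else data.table::as.data.table(annotation)
  stopifnot(all(c("snv_id", "gene", "category") %in% names(ann)))
  s <- merge(s, ann[, .(snv_id, gene, category)], by = "snv_id",
             all.x = FALSE)
  if (nrow(s) == 0L)
    return(data.table::data.table(
      gene = character(0), minR = integer(0), n_snvs = integer(0),
      n_intronic = integer(0), n_non_intronic = integer(0),
      mean_frac_biallelic = numeric(0),
      mean_frac_biallelic_intronic = numeric(0),
      mean_frac_biallelic_non_intronic = numeric(0),
      concordance = numeric(0), pattern = character(0)))

  majority <- function(p) {
    p <- p[p != "insufficient_cells"]
    if (!length(p)) return("insufficient_cells")
    tab <- sort(table(p), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) "discordant"
    else names(tab)[1L]
  }
  out <- s[, {
    fb <- frac_biallelic[!is.na(frac_biallelic)]
    intr <- category == "intron"
    .(n_snvs = .N,
      n_intronic = sum(intr), n_non_intronic = sum(!intr),
      mean_frac_biallelic = if (length(fb)) mean(fb) else NA_real_,
      mean_frac_biallelic_intronic =
        if (any(intr & !is.na(frac_biallelic)))
          mean(frac_biallelic[intr], na.rm = TRUE) else NA_real_,
      mean_frac_biallelic_non_intronic =
        if (any(!intr & !is.na(frac_biallelic)))
          mean(frac_biallelic[!intr], na.rm = TRUE) else NA_real_,
      concordance = if (length(fb)) max(fb) - min(fb) else NA_real_,
      pattern = majority(pattern))
  }, by = .(gene, minR)]
  data.table::setorderv(out, c("gene", "minR"))
  out[]
}

#' Chi-square test of a 2x2 contingency table, no continuity correction
#'
#' Pearson's statistic sum((O - E)^2 / E) with 1 degree of freedom, as used
#' for the intronic versus non-intronic bi-allelic comparison.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @return list(statistic, p_value).
#' @export
allelic_chisq <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    .stop_data("allelic_chisq expects a 2x2 table")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Intronic versus non-intronic bi-allelic expression
#'
#' Pools the per-cell VAF_RNA measurements at one minR into a 2x2 table of
#' (bi-allelic vs not) x (intronic vs non-intronic SNV) and tests
#' independence with an uncorrected chi-square.  A measurement is bi-allelic
#' when lower < VAF < upper.
#'
#' @param estimates output of \code{\link{estimate_vaf}} at one minR.
#' @param annotation table (or TSV path) with snv_id, category.
#' @param cfg a \code{\link{classification_config}} (for lower/upper).
#' @return list(applicable, table, statistic, p_value, prop_biallelic); when
#'   either group is empty, \code{applicable = FALSE} and the test fields are
#'   NA.
#' @export
compare_intronic <- function(estimates, annotation,
                             cfg = classification_config()) {
  stopifnot(inherits(cfg, "scvaf_classification_config"))
  est <- data.table::as.data.table(estimates)
  ann <- if (is.character(annotation)) data.table::fread(annotation)
         else data.table::as.data.table(annotation)
  est <- merge(est, ann[, .(snv_id, category)], by = "snv_id")
  est[, intronic := category == "intron"]
  est[, biallelic := vaf > cfg$lower & vaf < cfg$upper]
  if (!any(est$intronic) || !any(!est$intronic))
    return(list(applicable = FALSE, table = NULL, statistic = NA_real_,
                p_value = NA_real_, prop_biallelic = c(intronic = NA_real_,
                                                       non_intronic = NA_real_)))
  tab <- matrix(c(sum(est$intronic & est$biallelic),
                  sum(est$intronic & !est$biallelic),
                  sum(!est$intronic & est$biallelic),
                  sum(!est$intronic & !est$biallelic)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("intronic", "non_intronic"),
                                c("biallelic", "not_biallelic")))
  ht <- allelic_chisq(tab)
  list(applicable = TRUE, table = tab,
       statistic = ht$statistic, p_value = ht$p_value,
       prop_biallelic = c(
         intronic = tab[1, 1] / sum(tab[1, ]),
         non_intronic = tab[2, 1] / sum(tab[2, ])))
}

#' Histogram of per-cell VAF_RNA estimates
#'
#' Bins the estimates with dedicated point bins for strict monoallelic
#' expression: \{0\}, (0, 0.1], ..., (0.9, 1), \{1\} at the default bin
#' width 0.1.  Strictness is decided on the counts (n_var == 0 / n_ref == 0)
#' when available.
#'
#' @param estimates output of \code{\link{estimate_vaf}}, or a numeric vector
#'   of VAF values in [0, 1].
#' @param bin_width interior bin width; 1 / bin_width must be an integer.
#' @return data.table (bin, lower, upper, count); counts sum to the number of
#'   estimates.
#' @export
vaf_histogram <- function(estimates, bin_width = 0.1) {
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    .stop_config("1 / bin_width must be an integer")
  nb <- as.integer(round(nb))
  if (is.numeric(estimates)) {
    vaf <- estimates
    zero <- vaf == 0
    one <- vaf == 1
  } else {
    est <- data.table::as.data.table(estimates)
    vaf <- est$vaf
    zero <- est$n_var == 0L
    one <- est$n_ref == 0L
  }
  interior <- vaf[!zero & !one]
  breaks <- seq(0, 1, length.out = nb + 1L)
  cnt <- as.integer(table(cut(interior, breaks = breaks, right = TRUE,
                              include.lowest = FALSE)))
  lab <- c("0",
           sprintf("(%s,%s%s", format(breaks[-(nb + 1L)]),
                   format(breaks[-1L]),
                   c(rep("]", nb - 1L), ")")),
           "1")
  data.table::data.table(
    bin = lab,
    lower = c(0, breaks[-(nb + 1L)], 1),
    upper = c(0, breaks[-1L], 1),
    count = c(sum(zero), cnt, sum(one)))
}
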