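# VAF_RNA estimation, per-SNV summaries, pattern classification, gene-level
# aggregation, intronic comparison, histograms.

test_that("estimate_vaf applies the formula and the minR gate", {
  counts <- rbind(count_row("c1", "s1", 7, 3),    # depth 10
                  count_row("c2", "s1", 7, 2),    # depth 9
                  count_row("c3", "s1", 0, 3))    # monoallelic extreme
  e10 <- estimate_vaf(counts, 10)
  expect_equal(nrow(e10), 1L)
  expect_equal(e10$vaf, 0.3)
  expect_equal(e10$depth_informative, 10L)
  e3 <- estimate_vaf(counts, 3)
  expect_equal(e3[cell_barcode == "c3", vaf], 1.0)
  expect_equal(nrow(e3), 3L)
  # n_other never enters the denominator
  co <- count_row("c1", "s1", 5, 5, n_other = 90)
  expect_equal(estimate_vaf(co, 10)$vaf, 0.5)
  expect_equal(nrow(estimate_vaf(co, 11)), 0L)
  expect_error(estimate_vaf(counts, 0), class = "scvaf_config_error")
})

test_that("summarize_snv computes statistics and honours min_cells_stats", {
  cfg <- classification_config(min_cells_pattern = 10L)
  # 10 cells all VAF 0.5
  counts <- count_row(sprintf("c%02d", 1:10), "s1", 5, 5)
  s <- summarize_snv(estimate_vaf(counts, 3), cfg)
  expect_equal(s$n_cells, 10L)
  expect_equal(s$mean_vaf, 0.5)
  expect_equal(s$median_vaf, 0.5)
  expect_equal(s$frac_biallelic, 1.0)
  expect_equal(s$frac_strict_mono, 0.0)
  expect_equal(s$pattern, "biallelic")
  # 9 cells: insufficient for statistics
  s9 <- summarize_snv(estimate_vaf(counts[1:9], 3), cfg)
  expect_equal(s9$pattern, "insufficient_cells")
  expect_true(is.na(s9$frac_biallelic))
  # median midpoint rule for even n
  ce <- rbind(count_row("c1", "s1", 6, 4), count_row("c2", "s1", 4, 6),
              count_row(sprintf("d%d", 1:8), "s1", 5, 5))
  expect_equal(summarize_snv(estimate_vaf(ce, 3), cfg)$median_vaf, 0.5)
})

test_that("boundary VAFs 0.2/0.8 count as predominantly monoallelic", {
  cfg <- classification_config(min_cells_pattern = 10L)
  counts <- rbind(count_row(sprintf("a%02d", 1:5), "s1", 8, 2),   # vaf 0.2
                  count_row(sprintf("b%02d", 1:5), "s1", 2, 8))   # vaf 0.8
  s <- summarize_snv(estimate_vaf(counts, 10), cfg)
  expect_equal(s$frac_predom_mono, 1.0)
  expect_equal(s$frac_biallelic, 0.0)
  expect_equal(s$frac_strict_mono, 0.0)
})

test_that("partition identity holds on random inputs (property)", {
  set.seed(19)
  for (rep in 1:20) {
    n_cells <- sample(10:60, 1)
    counts <- data.table::rbindlist(lapply(1:4, function(s) {
      d <- sample(3:12, n_cells, replace = TRUE)
      v <- rbinom(n_cells, d, runif(1))
      count_row(sprintf("c%03d", 1:n_cells), sprintf("s%d", s), d - v, v)
    }))
    s <- summarize_snv(estimate_vaf(counts, 3), classification_config())
    ok <- !is.na(s$frac_biallelic)
    expect_true(all(abs(s$frac_predom_mono[ok] + s$frac_biallelic[ok] - 1)
                    < 1e-12))
    expect_true(all(s$frac_strict_mono[ok] <= s$frac_predom_mono[ok] + 1e-12))
  }
})

test_that("classification rules: RME precedence, skew, biallelic", {
  cfg <- classification_config()
  row <- function(fb, fl, fh, n = 100L)
    data.table::data.table(n_cells = n, frac_biallelic = fb, frac_low = fl,
                           frac_high = fh)
  expect_equal(classify_pattern(row(0.02, 0.49, 0.49), cfg), "RME")
  expect_equal(classify_pattern(row(0.65, 0.05, 0.30), cfg), "skewed")
  expect_equal(classify_pattern(row(0.90, 0.05, 0.05), cfg), "biallelic")
  # both skew conditions must hold
  expect_equal(classify_pattern(row(0.85, 0.05, 0.10), cfg), "biallelic")
  expect_equal(classify_pattern(row(0.60, 0.20, 0.20), cfg), "biallelic")
  # under 50 cells: no pattern call
  expect_equal(classify_pattern(row(0.02, 0.49, 0.49, n = 49L), cfg),
               "insufficient_cells")
})

test_that("strict-monoallelic fraction matches the exact binomial oracle", {
  # 200 cells, depth 10, p = 0.5: frac_strict ~ 2 * 0.5^10
  set.seed(31)
  d <- 10L
  v <- rbinom(200, d, 0.5)
  counts <- count_row(sprintf("c%03d", 1:200), "s1", d - v, v)
  s <- summarize_snv(estimate_vaf(counts, d), classification_config())
  p_strict <- 2 * 0.5^d
  se <- sqrt(p_strict * (1 - p_strict) / 200)
  expect_lt(abs(s$frac_strict_mono - p_strict), 3 * se + 1e-12)
})

test_that("gene aggregation: singleton, arithmetic, majority vote", {
  ann <- data.table::data.table(
    snv_id = c("s1", "s2", "s3", "s4"),
    gene = c("GA", "GB", "GB", "GB"),
    category = c("utr3", "intron", "utr3", "coding"))
  s <- data.table::data.table(
    snv_id = c("s1", "s2", "s3", "s4"), minR = 3L,
    n_cells = 100L,
    frac_biallelic = c(0.9, 0.88, 0.9, 0.02),
    frac_low = 0.05, frac_high = 0.05,
    pattern = c("biallelic", "biallelic", "biallelic", "RME"))
  g <- aggregate_gene(s, ann)
  expect_equal(g[gene == "GA", concordance], 0)
  expect_equal(g[gene == "GA", pattern], "biallelic")
  expect_equal(g[gene == "GB", concordance], 0.88, tolerance = 1e-12)
  expect_equal(g[gene == "GB", pattern], "biallelic")   # 2 vs 1 vote
  expect_equal(g[gene == "GB", n_intronic], 1L)
  expect_equal(g[gene == "GB", mean_frac_biallelic_intronic], 0.88)
  # tie -> discordant
  s2 <- s[snv_id %in% c("s3", "s4")]
  expect_equal(aggregate_gene(s2, ann)[gene == "GB", pattern], "discordant")
  # two-SNV arithmetic: |0.9 - 0.88|
  expect_equal(aggregate_gene(s[1:3], ann)[gene == "GB", concordance], 0.02,
               tolerance = 1e-12)
})

test_that("chi-square: hand-computed statistic, no continuity correction", {
  # independent table
  flat <- allelic_chisq(matrix(c(50, 50, 50, 50), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # hand computation of sum((O-E)^2/E) for [[30,70],[70,30]]
  tab <- matrix(c(30, 70, 70, 30), 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - E)^2 / E)
  expect_equal(hand, 32)                       # oracle check
  got <- allelic_chisq(tab)
  expect_equal(got$statistic, 32)
  expect_lt(got$p_value, 1e-7)
})

test_that("compare_intronic pools measurements and flags empty groups", {
  ann <- data.table::data.table(snv_id = c("si", "se"),
                                category = c("intron", "utr3"))
  counts <- rbind(count_row(sprintf("c%02d", 1:20), "si", 5, 0),
                  count_row(sprintf("c%02d", 1:20), "se", 3, 2))
  est <- estimate_vaf(counts, 3)
  res <- compare_intronic(est, ann)
  expect_true(res$applicable)
  expect_equal(unname(res$prop_biallelic["intronic"]), 0)
  expect_equal(unname(res$prop_biallelic["non_intronic"]), 1)
  expect_equal(sum(res$table), 40)
  # empty group -> not applicable
  res2 <- compare_intronic(est[snv_id == "si"], ann)
  expect_false(res2$applicable)
  expect_true(is.na(res2$statistic))
})

test_that("histogram bins: point masses at 0 and 1, interior placement", {
  h <- vaf_histogram(c(0, 0.05, 1))
  expect_equal(nrow(h), 12L)
  expect_equal(h[bin == "0", count], 1L)
  expect_equal(h$count[2], 1L)            # (0, 0.1]
  expect_equal(h[bin == "1", count], 1L)
  expect_equal(sum(h$count), 3L)
  # uniform interior grid: one per interior bin
  h2 <- vaf_histogram(seq(0.05, 0.95, by = 0.1))
  expect_equal(h2$count, c(0L, rep(1L, 10L), 0L))
  # count-backed estimates decide strictness on integers
  counts <- rbind(count_row("c1", "s1", 0, 5), count_row("c2", "s1", 5, 0),
                  count_row("c3", "s1", 1, 9))
  h3 <- vaf_histogram(estimate_vaf(counts, 3))
  expect_equal(h3[bin == "0", count], 1L)
  expect_equal(h3[bin == "1", count], 1L)
  expect_equal(sum(h3$count), 3L)
  expect_error(vaf_histogram(c(0.5), bin_width = 0.3),
               class = "scvaf_config_error")
})

test_that("minR monotonicity of strict-monoallelic fraction on binomial data", {
  cfg <- sim_config(seed = 37, n_cells = 300, n_genes = 4, snvs_per_gene = 2,
                    depth_model = list(kind = "poisson", lambda = 12))
  tr <- simulate_counts(cfg)
  fr <- vapply(c(3L, 5L, 10L), function(mr)
    allelic_fractions(estimate_vaf(tr$counts, mr))["strict"], numeric(1))
  expect_true(fr[1] >= fr[2] && fr[2] >= fr[3])
})
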