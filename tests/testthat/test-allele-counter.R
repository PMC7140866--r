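# Barcoded pileup counting and UMI deduplication.

contigs1 <- c(chr1 = 1000L)

test_that("direct counting at a locus, with and without PCR duplicates", {
  base_reads <- rbind(
    locus_read("G", "CELL1", "UMI01"), locus_read("G", "CELL1", "UMI02"),
    locus_read("G", "CELL1", "UMI03"), locus_read("A", "CELL1", "UMI04"),
    locus_read("A", "CELL1", "UMI05"))
  sam <- write_test_sam(base_reads, contigs1)
  out <- count_alleles(sam, test_snv(), min_map_qual = 30)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_ref, 2L)
  expect_equal(out$n_var, 3L)
  expect_equal(out$n_other, 0L)

  # every molecule duplicated 4x (same CB+UB): identical counts
  dup <- base_reads[rep(seq_len(nrow(base_reads)), each = 4L)]
  dup[, qname := sprintf("d%04d", .I)]
  out2 <- count_alleles(write_test_sam(dup, contigs1), test_snv())
  expect_equal(out2$n_ref, 2L)
  expect_equal(out2$n_var, 3L)
})

test_that("dedup keeps the highest mapping quality read per UMI", {
  # same UMI, MAPQ 255 (alt) vs 30 (ref): the alt read survives
  reads <- rbind(locus_read("G", "CELL1", "UMIxx", mapq = 255L),
                 locus_read("A", "CELL1", "UMIxx", mapq = 30L))
  out <- count_alleles(write_test_sam(reads, contigs1), test_snv())
  expect_equal(out$n_var, 1L)
  expect_equal(out$n_ref, 0L)

  # three distinct UMIs -> three molecules
  r3 <- rbind(locus_read("G", "CELL1", "U1"), locus_read("G", "CELL1", "U2"),
              locus_read("A", "CELL1", "U3"))
  out3 <- count_alleles(write_test_sam(r3, contigs1), test_snv())
  expect_equal(out3$n_var + out3$n_ref, 3L)
})

test_that("dedup_umis matches the brute-force oracle on random read sets", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(1:25, 1)
    reads <- data.table::data.table(
      umi = sample(sprintf("U%02d", 1:8), n, replace = TRUE),
      mapq = sample(c(0L, 30L, 60L, 255L), n, replace = TRUE),
      pos = sample(90:110, n, replace = TRUE),
      qname = sample(sprintf("q%03d", 1:500), n),
      base = sample(c("A", "G"), n, replace = TRUE))
    got <- dedup_umis(reads)
    want <- dedup_oracle(reads)
    expect_equal(as.data.frame(got[order(umi)]),
                 as.data.frame(want),
                 ignore_attr = TRUE)
  }
  # empty input -> empty output
  expect_equal(nrow(dedup_umis(data.table::data.table(
    umi = character(0), mapq = integer(0), pos = integer(0),
    qname = character(0)))), 0L)
})

test_that("quality, tag and whitelist filters drop the right reads", {
  reads <- rbind(
    locus_read("G", "CELL1", "U1", mapq = 60L),
    locus_read("G", "CELL1", "U2", mapq = 10L),          # below min mapq
    locus_read("G", "CELL1", "U3", vW = 2L),             # WASP-failing
    locus_read("G", "CELL1", "U4", vW = 1L),             # WASP-passing
    locus_read("G", "CELL2", "U5"))                      # other cell
  sam <- write_test_sam(reads, contigs1)
  snv <- test_snv()

  out <- count_alleles(sam, snv, min_map_qual = 30)
  expect_equal(out[cell_barcode == "CELL1", n_var], 2L)  # U1 + U4
  expect_equal(out[cell_barcode == "CELL2", n_var], 1L)

  out_nowasp <- count_alleles(sam, snv, min_map_qual = 30,
                              honor_wasp_tag = FALSE)
  expect_equal(out_nowasp[cell_barcode == "CELL1", n_var], 3L)

  out_wl <- count_alleles(sam, snv, barcode_whitelist = "CELL2")
  expect_equal(out_wl$cell_barcode, "CELL2")

  # whitelist monotonicity: growing the whitelist never shrinks counts
  out_all <- count_alleles(sam, snv,
                           barcode_whitelist = c("CELL1", "CELL2"))
  expect_true(all(out_all[cell_barcode == "CELL2", .(n_ref, n_var)] ==
                    out_wl[, .(n_ref, n_var)]))
  expect_gte(nrow(out_all), nrow(out_wl))
})

test_that("N bases count as other; deletions and low base quality drop", {
  reads <- rbind(
    locus_read("N", "CELL1", "U1"),
    locus_read("G", "CELL1", "U2"),
    # deletion spanning the SNV position: 5M2D5M starting at 97 deletes
    # positions 102-103... place it so position 100 falls in the deletion
    data.table::data.table(chrom = "chr1", pos = 96L, mapq = 60L,
                           cigar = "4M2D6M", seq = "AAAAGGGGGG",
                           cb = "CELL1", ub = "U3", qname = "qdel",
                           vW = NA_integer_))
  sam <- write_test_sam(reads, contigs1)
  out <- count_alleles(sam, test_snv())
  expect_equal(out$n_other, 1L)   # the N
  expect_equal(out$n_var, 1L)
  expect_equal(out$n_ref, 0L)     # deletion contributes nothing

  # base quality below threshold: read ignored
  lowq <- locus_read("G", "CELL1", "U9")
  lowq[, qual := paste0("IIIII", "#", "IIII")]  # Q2 at the SNV position
  out2 <- count_alleles(write_test_sam(lowq, contigs1), test_snv(),
                        min_base_qual = 20)
  expect_equal(nrow(out2), 0L)
})

test_that("counting is invariant to record order and idempotent under dedup", {
  set.seed(7)
  reads <- rbindlist_shuffled <- data.table::rbindlist(lapply(1:30, function(i)
    locus_read(sample(c("A", "G"), 1), sample(c("C1", "C2", "C3"), 1),
               sprintf("U%02d", sample(1:10, 1)),
               mapq = sample(c(30L, 60L, 255L), 1),
               qname = sprintf("q%03d", i))))
  sam1 <- write_test_sam(reads, contigs1)
  sam2 <- write_test_sam(reads[sample(.N)], contigs1)
  o1 <- count_alleles(sam1, test_snv())
  o2 <- count_alleles(sam2, test_snv())
  expect_equal(o1, o2)

  # feeding back the deduplicated molecule set reproduces the counts
  surv <- dedup_umis(reads[cb == "C1"][, .(umi = ub, mapq, pos, qname,
                                           chrom, cigar, seq, cb, ub)])
  sam3 <- write_test_sam(surv[, .(chrom, pos, mapq, cigar, seq, cb, ub,
                                  qname)], contigs1)
  o3 <- count_alleles(sam3, test_snv())
  expect_equal(o3, o1[cell_barcode == "C1"])
})

test_that("contigs absent from the header and missing files error", {
  reads <- locus_read("G", "CELL1", "U1")
  sam <- write_test_sam(reads, contigs1)
  bad_snv <- test_snv(chrom = "chrZ")
  expect_error(count_alleles(sam, bad_snv), class = "scvaf_data_error")
  expect_error(count_alleles("/nonexistent.bam", test_snv()),
               class = "scvaf_data_error")
})

test_that("pool_counts sums per SNV and handles empty input", {
  counts <- rbind(count_row("C1", "snvA", 2, 3), count_row("C2", "snvA", 0, 5),
                  count_row("C1", "snvB", 1, 1))
  pooled <- pool_counts(counts)
  expect_equal(pooled[snv_id == "snvA", .(N_ref, N_var)],
               data.table::data.table(N_ref = 2L, N_var = 8L))
  expect_equal(nrow(pool_counts(counts[0])), 0L)
})

test_that("counter reproduces simulator truth exactly (small end-to-end)", {
  cfg <- sim_config(seed = 33, n_cells = 25, n_genes = 3, snvs_per_gene = 2,
                    depth_model = list(kind = "poisson", lambda = 4),
                    class_fractions = c(symmetric = 0.7, RME = 0.3),
                    pcr_duplication_rate = 2, wasp_fail_rate = 0.1)
  out <- withr::local_tempdir()
  tr <- simulate_dataset(cfg, out)
  snvs <- read_snv_vcf(tr$paths$vcf)
  got <- count_alleles(tr$paths$alignment, snvs)
  want <- tr$counts
  data.table::setorderv(want, c("snv_id", "cell_barcode"))
  expect_equal(got[, .(cell_barcode, snv_id, n_ref, n_var)],
               want[, .(cell_barcode, snv_id, n_ref, n_var)])
  # ignoring the WASP tag inflates counts
  got_nowasp <- count_alleles(tr$paths$alignment, snvs,
                              honor_wasp_tag = FALSE)
  expect_gt(sum(got_nowasp$n_ref + got_nowasp$n_var + got_nowasp$n_other),
            sum(got$n_ref + got$n_var))
})
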