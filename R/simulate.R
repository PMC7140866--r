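# Synthetic 10x-style allele data with known truth.
#
# One toy contig per gene; SNVs are spaced 2*read_length apart so that a read
# generated for one locus can never overlap another, which keeps the truth
# table an exact oracle for the counter.

# ---- generative core (assumes the RNG seed is already set) -----------------

.sim_snvs <- function(cfg) {
  rl <- cfg$read_length
  n_snv_total <- cfg$n_genes * cfg$snvs_per_gene
  contig_len <- 2L * rl * (cfg$snvs_per_gene + 1L)
  genes <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  seqs <- .rand_dna(cfg$n_genes, contig_len)

  snvs <- data.table::CJ(gene_idx = seq_len(cfg$n_genes),
                         k = seq_len(cfg$snvs_per_gene), sorted = TRUE)
  snvs[, chrom := genes[gene_idx]]
  snvs[, gene := chrom]
  snvs[, pos := 2L * rl * k]
  snvs[, ref := substr(seqs[gene_idx], pos, pos)]
  other <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
  pick <- sample.int(3L, nrow(snvs), replace = TRUE)
  snvs[, alt := substr(other[ref], pick, pick)]
  snvs[, snv_id := .snv_id(chrom, pos, ref, alt)]

  is_intron <- runif(nrow(snvs)) < cfg$fraction_intronic_snvs
  other_cat <- sample(c("utr3", "coding", "utr5"), nrow(snvs),
                      replace = TRUE, prob = c(0.6, 0.3, 0.1))
  snvs[, category := ifelse(is_intron, "intron", other_cat)]

  cls <- sample(names(cfg$class_fractions), nrow(snvs), replace = TRUE,
                prob = cfg$class_fractions)
  snvs[, class := cls]
  p <- rep(0.5, nrow(snvs))
  skew_side <- runif(nrow(snvs)) < 0.5
  p[cls == "skewed"] <- ifelse(skew_side[cls == "skewed"],
                               cfg$skew_p, 1 - cfg$skew_p)
  mono_side <- runif(nrow(snvs)) < 0.5
  p[cls == "strict_mono"] <- as.numeric(mono_side[cls == "strict_mono"])
  snvs[, p_true := p]

  # engineered VCF-filter failures, assigned to distinct random SNVs
  snvs[, vcf_fail := "none"]
  n_fail <- sum(cfg$vcf_fail)
  if (n_fail > 0) {
    idx <- sample.int(nrow(snvs), n_fail)
    snvs$vcf_fail[idx] <- rep(names(cfg$vcf_fail), cfg$vcf_fail)
  }
  snvs[, qual := ifelse(vcf_fail == "qual", 50, 200)]
  snvs[, mq   := ifelse(vcf_fail == "mq",   55, 60.5)]
  snvs[, qd   := ifelse(vcf_fail == "qd",    1, 3)]
  snvs[, fs   := ifelse(vcf_fail == "fs",  6.5, 0)]
  snvs[, snv_idx := seq_len(.N)]
  list(snvs = snvs, contigs = genes, contig_seqs = seqs,
       contig_len = contig_len)
}

.sim_cells <- function(cfg) {
  bc <- .rand_dna_unique(rep(1L, cfg$n_cells), cfg$barcode_length)
  cells <- data.table::data.table(cell_idx = seq_len(cfg$n_cells),
                                  barcode = bc, reason = "none")
  n_bad <- cfg$n_bad_cells_low_genes + cfg$n_bad_cells_high_mito
  if (n_bad > 0) {
    bad <- sample.int(cfg$n_cells, n_bad)
    cells$reason[bad[seq_len(cfg$n_bad_cells_low_genes)]] <- "low_genes"
    if (cfg$n_bad_cells_high_mito > 0)
      cells$reason[bad[cfg$n_bad_cells_low_genes +
                         seq_len(cfg$n_bad_cells_high_mito)]] <- "high_mito"
  }
  cells[, qc_fail := reason != "none"]
  cells
}

.sim_depth <- function(n, dm, scale) {
  switch(dm$kind,
         fixed   = as.integer(round(dm$n * scale)),
         poisson = rpois(n, dm$lambda * scale),
         nb      = rnbinom(n, size = dm$dispersion, mu = dm$mean * scale))
}

# per-(cell, SNV) truth molecule counts
.sim_pairs <- function(cfg, snvs, cells) {
  pairs <- data.table::CJ(cell_idx = cells$cell_idx,
                          snv_idx = snvs$snv_idx, sorted = TRUE)
  scale <- ifelse(snvs$category[pairs$snv_idx] == "intron",
                  cfg$intron_depth_scale, 1)
  pairs[, depth := .sim_depth(.N, cfg$depth_model, scale)]
  pairs <- pairs[depth > 0L]

  cls <- snvs$class[pairs$snv_idx]
  p <- snvs$p_true[pairs$snv_idx]
  na <- integer(nrow(pairs))

  i <- cls == "symmetric"
  if (any(i)) {
    if (is.finite(cfg$overdispersion)) {
      pc <- rbeta(sum(i), cfg$overdispersion / 2, cfg$overdispersion / 2)
      na[i] <- rbinom(sum(i), pairs$depth[i], pc)
    } else {
      na[i] <- rbinom(sum(i), pairs$depth[i], 0.5)
    }
  }
  i <- cls == "skewed"
  if (any(i)) na[i] <- rbinom(sum(i), pairs$depth[i], p[i])
  i <- cls == "RME"
  if (any(i)) na[i] <- pairs$depth[i] * (runif(sum(i)) < 0.5)
  i <- cls == "strict_mono"
  if (any(i)) na[i] <- as.integer(round(pairs$depth[i] * p[i]))

  pairs[, n_alt := na]
  pairs[, n_ref := depth - n_alt]
  pairs[]
}

.sim_core <- function(cfg) {
  s <- .sim_snvs(cfg)
  cells <- .sim_cells(cfg)
  pairs <- .sim_pairs(cfg, s$snvs, cells)
  counts <- data.table::data.table(
    cell_barcode = cells$barcode[pairs$cell_idx],
    snv_id = s$snvs$snv_id[pairs$snv_idx],
    n_ref = pairs$n_ref, n_var = pairs$n_alt, n_other = 0L)
  data.table::setorderv(counts, c("snv_id", "cell_barcode"))
  list(snvs = s$snvs, cells = cells, pairs = pairs, counts = counts,
       contigs = s$contigs, contig_seqs = s$contig_seqs,
       contig_len = s$contig_len)
}

#' In-memory synthetic truth (no files written)
#'
#' Runs the same seeded generative model as \code{\link{simulate_dataset}} but
#' stops at the truth tables, skipping read/file emission.  Useful for
#' analytic checks of the downstream VAF machinery at scales where emitting a
#' SAM file would be wasteful.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{snvs}, \code{cells} and \code{counts} (an
#'   allele-count table of true unique-molecule counts).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "scvaf_sim_config"))
  set.seed(config$seed)
  core <- .sim_core(config)
  list(snvs = core$snvs[], cells = core$cells[], counts = core$counts[])
}

# ---- molecule -> read records ---------------------------------------------

.sim_records <- function(cfg, core) {
  pairs <- core$pairs
  nmol_by_pair <- pairs$depth
  mol <- pairs[rep(seq_len(.N), depth), .(cell_idx, snv_idx)]
  within_idx <- sequence(nmol_by_pair)
  mol[, allele := ifelse(within_idx <= rep(pairs$n_alt, nmol_by_pair),
                         "alt", "ref")]
  mol[, umi := .rand_dna_unique(paste(cell_idx, snv_idx), cfg$umi_length)]
  mol[, mol_id := seq_len(.N)]

  copies <- 1L + rpois(nrow(mol), cfg$pcr_duplication_rate)
  rec <- mol[rep(seq_len(.N), copies)]
  rec[, is_primary := sequence(copies) == 1L]
  rec[, mapq := ifelse(is_primary, 255L,
                       sample(c(20L, 40L, 60L, 255L), .N, replace = TRUE))]
  rec[, vW := NA_integer_]

  # WASP-failing extras: fresh UMIs so the truth molecule set is untouched
  n_wasp <- round(cfg$wasp_fail_rate * nrow(mol))
  if (n_wasp > 0) {
    wi <- sample.int(nrow(mol), n_wasp, replace = TRUE)
    w <- mol[wi, .(cell_idx, snv_idx)]
    w[, allele := sample(c("ref", "alt"), .N, replace = TRUE)]
    taken <- unique(rec[, paste(cell_idx, snv_idx, umi)])
    wumi <- .rand_dna(n_wasp, cfg$umi_length)
    repeat {
      clash <- duplicated(paste(w$cell_idx, w$snv_idx, wumi)) |
        paste(w$cell_idx, w$snv_idx, wumi) %in% taken
      if (!any(clash)) break
      wumi[clash] <- .rand_dna(sum(clash), cfg$umi_length)
    }
    w[, umi := wumi]
    w[, mol_id := NA_integer_]
    w[, is_primary := FALSE]
    w[, mapq := 255L]
    w[, vW := 2L]
    rec <- data.table::rbindlist(list(rec, w), use.names = TRUE)
  }

  snvs <- core$snvs
  rec[, base := ifelse(allele == "alt", snvs$alt[snv_idx], snvs$ref[snv_idx])]
  if (cfg$base_error_rate > 0) {
    err <- runif(nrow(rec)) < cfg$base_error_rate
    if (any(err)) {
      bases <- c("A", "C", "G", "T")
      cur <- rec$base[err]
      sub <- vapply(cur, function(b) sample(setdiff(bases, b), 1L),
                    character(1))
      rec$base[err] <- sub
    }
  }
  rec[, offset := sample.int(cfg$read_length, .N, replace = TRUE) - 1L]
  rec[, pos := snvs$pos[snv_idx]]
  rec[, start_pos := pos - offset]
  rec[, chrom := snvs$chrom[snv_idx]]
  rec[, record_id := seq_len(.N)]
  rec[]
}

.sam_lines <- function(cfg, core, rec) {
  rl <- cfg$read_length
  seqs <- core$contig_seqs[match(rec$chrom, core$contigs)]
  read_seq <- substr(seqs, rec$start_pos, rec$start_pos + rl - 1L)
  read_seq <- paste0(substr(read_seq, 1L, rec$offset), rec$base,
                     substr(read_seq, rec$offset + 2L, rl))
  qual <- strrep("F", rl)  # Q37 throughout
  cb <- core$cells$barcode[rec$cell_idx]
  qname <- sprintf("r%08d", rec$record_id)
  tags <- paste0("CB:Z:", cb, "\tUB:Z:", rec$umi)
  tags <- ifelse(is.na(rec$vW), tags, paste0(tags, "\tvW:i:", rec$vW))
  body <- paste(qname, 0L, rec$chrom, rec$start_pos, rec$mapq,
                paste0(rl, "M"), "*", 0L, 0L, read_seq, qual, tags,
                sep = "\t")
  ord <- order(match(rec$chrom, core$contigs), rec$start_pos, qname,
               method = "radix")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", core$contigs, core$contig_len))
  c(header, body[ord])
}

.vcf_lines <- function(core) {
  snvs <- core$snvs
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=scvaf-simulator",
    sprintf("##contig=<ID=%s,length=%d>", core$contigs, core$contig_len),
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred strand bias\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(match(snvs$chrom, core$contigs), snvs$pos, method = "radix")
  s <- snvs[ord]
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t%.2f\t.\tMQ=%.2f;QD=%.2f;FS=%.3f",
                  s$chrom, s$pos, s$snv_id, s$ref, s$alt, s$qual,
                  s$mq, s$qd, s$fs)
  c(header, body)
}

# engineered gene-by-cell matrix; detected-gene and mito-% targets per cell
.sim_matrix <- function(cfg, core) {
  n_bg <- cfg$n_matrix_genes - cfg$n_genes
  gene_names <- c(core$contigs,
                  if (n_bg > 0) sprintf("BG%05d", seq_len(n_bg)),
                  sprintf("MT-%02d", seq_len(cfg$n_mito_genes)))
  n_nonmito <- cfg$n_matrix_genes
  mito_rows <- n_nonmito + seq_len(cfg$n_mito_genes)
  cells <- core$cells

  lo_min <- max(10L, cfg$qc_target_genes %/% 5L)
  lo_max <- cfg$qc_target_genes - 500L
  hi_min <- cfg$qc_target_genes + 50L
  hi_max <- min(n_nonmito, cfg$qc_target_genes + 400L)

  is <- js <- xs <- vector("list", nrow(cells))
  detected <- integer(nrow(cells))
  pct <- numeric(nrow(cells))
  for (c in seq_len(nrow(cells))) {
    low <- cells$reason[c] == "low_genes"
    d <- if (low) sample(lo_min:lo_max, 1L) else sample(hi_min:hi_max, 1L)
    gi <- sort(sample.int(n_nonmito, d))
    x <- 1L + rpois(d, 0.6)
    tot <- sum(x)
    pt <- if (cells$reason[c] == "high_mito") cfg$qc_fail_pct_mito
          else cfg$qc_target_pct_mito
    m_tot <- round(pt / (100 - pt) * tot)
    if (m_tot > 0) {
      mbase <- m_tot %/% cfg$n_mito_genes
      mx <- rep(mbase, cfg$n_mito_genes)
      mx[1L] <- mx[1L] + m_tot - sum(mx)
      keep <- mx > 0
      gi <- c(gi, mito_rows[keep])
      x <- c(x, mx[keep])
    }
    is[[c]] <- gi
    js[[c]] <- rep(c, length(gi))
    xs[[c]] <- x
    detected[c] <- length(gi)
    pct[c] <- if (m_tot > 0) 100 * m_tot / (tot + m_tot) else 0
  }
  mat <- Matrix::sparseMatrix(i = unlist(is), j = unlist(js), x = unlist(xs),
                              dims = c(length(gene_names), nrow(cells)),
                              dimnames = list(gene_names, cells$barcode))
  list(matrix = mat, n_genes_detected = detected, pct_mito = pct)
}

# ---- public entry ----------------------------------------------------------

#' Simulate a complete synthetic single-cell allele dataset
#'
#' Writes, under \code{output_dir}: a toy reference (\code{reference.fasta},
#' one contig per gene), a coordinate-sorted tagged alignment
#' (\code{alignment.sam}; single-end, exact-match CIGAR, tags \code{CB:Z},
#' \code{UB:Z} and optionally \code{vW:i}), a VCF of candidate SNVs with
#' QUAL/MQ/QD/FS engineered per config (\code{snvs.vcf}), an annotation table
#' (\code{annotation.tsv}), a gene-by-cell MatrixMarket matrix with engineered
#' QC-failing cells (\code{matrix/}), and ground-truth tables
#' (\code{truth_*.tsv}).  PCR duplicates are extra records sharing a
#' molecule's (CB, UB) and position.  Identical seeds give byte-identical
#' outputs.
#'
#' Allelic classes per locus: \code{symmetric} draws alt molecules
#' (beta-)binomially at p = 0.5; \code{skewed} uses p = \code{skew_p} (side
#' chosen per locus); \code{RME} assigns each cell all-ref or all-alt by a
#' fair coin; \code{strict_mono} fixes p at 0 or 1 per locus.
#'
#' @param config a \code{\link{sim_config}}.
#' @param output_dir directory to create/write into.
#' @return invisibly, an object of class \code{scvaf_sim_truth}: list with
#'   \code{snvs}, \code{cells}, \code{counts} (true unique-molecule counts per
#'   cell and SNV), \code{matrix_qc} (true detected-gene / mito-% per cell)
#'   and \code{paths}.
#' @export
simulate_dataset <- function(config, output_dir) {
  stopifnot(inherits(config, "scvaf_sim_config"))
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    .stop_data("cannot create output directory: ", output_dir)

  set.seed(config$seed)
  core <- .sim_core(config)
  rec <- .sim_records(config, core)
  mx <- .sim_matrix(config, core)

  paths <- list(
    reference = file.path(output_dir, "reference.fasta"),
    alignment = file.path(output_dir, "alignment.sam"),
    vcf = file.path(output_dir, "snvs.vcf"),
    annotation = file.path(output_dir, "annotation.tsv"),
    matrix_dir = file.path(output_dir, "matrix"),
    truth_snvs = file.path(output_dir, "truth_snvs.tsv"),
    truth_cells = file.path(output_dir, "truth_cells.tsv"),
    truth_counts = file.path(output_dir, "truth_counts.tsv"))

  ref <- Biostrings::DNAStringSet(core$contig_seqs)
  names(ref) <- core$contigs
  Biostrings::writeXStringSet(ref, paths$reference)

  writeLines(.sam_lines(config, core, rec), paths$alignment)
  writeLines(.vcf_lines(core), paths$vcf)

  .write_tsv(core$snvs[, .(snv_id, chrom, pos, ref, alt, gene, category)],
             paths$annotation)

  dir.create(paths$matrix_dir, showWarnings = FALSE)
  Matrix::writeMM(mx$matrix, file.path(paths$matrix_dir, "matrix.mtx"))
  writeLines(rownames(mx$matrix), file.path(paths$matrix_dir, "features.tsv"))
  writeLines(colnames(mx$matrix), file.path(paths$matrix_dir, "barcodes.tsv"))

  cells_out <- core$cells[, .(barcode, qc_fail, reason)]
  cells_out[, n_genes_detected := mx$n_genes_detected]
  cells_out[, pct_mito := mx$pct_mito]
  .write_tsv(core$snvs[, .(snv_id, chrom, pos, ref, alt, gene, category,
                           class, p_true, vcf_fail, qual, mq, qd, fs)],
             paths$truth_snvs)
  .write_tsv(cells_out, paths$truth_cells)
  .write_tsv(core$counts, paths$truth_counts)

  truth <- structure(list(snvs = core$snvs[], cells = cells_out[],
                          counts = core$counts[],
                          n_records = nrow(rec), config = config,
                          paths = paths),
                     class = "scvaf_sim_truth")
  invisible(truth)
}

#' @export
print.scvaf_sim_truth <- function(x, ...) {
  cat(sprintf(
    "scvaf synthetic truth: %d cells, %d SNVs, %d (cell,SNV) pairs, %d reads\n",
    nrow(x$cells), nrow(x$snvs), nrow(x$counts), x$n_records))
  invisible(x)
}
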