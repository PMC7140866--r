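# Fixture builders shared across the suite.  Everything is generated in code
# at test time; nothing binary ships with the package.

# Minimal tagged SAM file from a read table.  Columns: chrom, pos (1-based
# alignment start), mapq, cigar, seq, cb, ub; optional qname, qual, vW.
write_test_sam <- function(reads, contigs, path = tempfile(fileext = ".sam")) {
  reads <- data.table::copy(data.table::as.data.table(reads))
  if (!"qname" %in% names(reads))
    reads[, qname := sprintf("q%04d", .I)]
  reads[is.na(qname), qname := sprintf("q%04d", which(is.na(reads$qname)))]
  if (!"qual" %in% names(reads))
    reads[, qual := strrep("I", nchar(seq))]   # Q40
  if (!"vW" %in% names(reads)) reads[, vW := NA_integer_]
  tags <- paste0("CB:Z:", reads$cb, "\tUB:Z:", reads$ub)
  tags <- ifelse(is.na(reads$vW), tags, paste0(tags, "\tvW:i:", reads$vW))
  body <- paste(reads$qname, 0L, reads$chrom, reads$pos, reads$mapq,
                reads$cigar, "*", 0L, 0L, reads$seq, reads$qual, tags,
                sep = "\t")
  ord <- order(match(reads$chrom, names(contigs)), reads$pos, reads$qname)
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                       as.integer(contigs)),
               body[ord]), path)
  path
}

# Reads of length 10 covering an SNV at `snvpos` with the given base at the
# locus (base sits at query position 6 when pos = snvpos - 5).
locus_read <- function(base, cb, ub, mapq = 60L, chrom = "chr1",
                       snvpos = 100L, qname = NULL, vW = NA_integer_) {
  data.table::data.table(
    chrom = chrom, pos = snvpos - 5L, mapq = mapq, cigar = "10M",
    seq = paste0("AAAAA", base, "AAAA"), cb = cb, ub = ub,
    qname = qname %||% NA_character_, vW = vW)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-locus SNV table matching locus_read()
test_snv <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "G") {
  data.table::data.table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         snv_id = paste(chrom, pos, ref, alt, sep = "_"))
}

# Brute-force UMI dedup oracle, independent of the package implementation:
# enumerate UMI groups, sort each by (-mapq, pos, qname) with base R, take
# the head.
dedup_oracle <- function(reads) {
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  keep <- lapply(split(seq_len(nrow(reads)), reads$umi), function(idx) {
    g <- reads[idx, ]
    idx[order(-g$mapq, g$pos, g$qname, method = "radix")][1]
  })
  out <- reads[sort(unlist(keep)), ]
  out[order(out$umi, method = "radix"), ]
}

# Allele-count rows in one call
count_row <- function(cell, snv, n_ref, n_var, n_other = 0L) {
  data.table::data.table(cell_barcode = cell, snv_id = snv,
                         n_ref = as.integer(n_ref),
                         n_var = as.integer(n_var),
                         n_other = as.integer(n_other))
}

# md5 fingerprint of a directory tree (relative names -> checksums)
tree_md5 <- function(dir) {
  f <- list.files(dir, recursive = TRUE)
  setNames(unname(tools::md5sum(file.path(dir, f))), f)
}
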