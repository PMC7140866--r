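# File-format plumbing: alignments via Rsamtools, VCF via VariantAnnotation,
# MatrixMarket via Matrix.

# Return a coordinate-sorted, indexed BAM for `path` (SAM or BAM).  SAM input
# is converted in a scratch directory; BAM input with a sibling .bai is used
# as-is, otherwise sorted+indexed into scratch.
.ensure_bam <- function(path, scratch = tempfile("scvaf_bam_")) {
  if (!file.exists(path)) .stop_data("alignment file not found: ", path)
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (!is_sam && file.exists(paste0(path, ".bai"))) return(path)
  dir.create(scratch, recursive = TRUE, showWarnings = FALSE)
  raw <- if (is_sam) {
    Rsamtools::asBam(path, file.path(scratch, "converted"),
                     overwrite = TRUE, indexDestination = FALSE)
  } else path
  sorted <- Rsamtools::sortBam(raw, file.path(scratch, "sorted"))
  Rsamtools::indexBam(sorted)
  sorted
}

#' Read candidate SNVs from a VCF
#'
#' Parses a VCF v4.x with \code{QUAL} and INFO keys \code{MQ}, \code{QD},
#' \code{FS} into a flat SNV table.  Only bi-allelic SNV records (single-base
#' REF and ALT) are kept; anything else is dropped with a warning, since the
#' analysis is confined to bi-allelic substitutions.  If an annotation table
#' is supplied, \code{gene} and \code{category} are joined by SNV id.
#'
#' @param path VCF file (plain or bgzipped).
#' @param annotation optional annotation table (or TSV path) with columns
#'   \code{snv_id}, \code{gene}, \code{category}.
#' @return data.table with columns chrom, pos, id, ref, alt, qual, mq, qd,
#'   fs, snv_id (chrom_pos_ref_alt) and, when annotated, gene and category.
#' @export
read_snv_vcf <- function(path, annotation = NULL) {
  if (!file.exists(path)) .stop_data("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) &
    nchar(alt1) == 1L & ref %in% c("A", "C", "G", "T") &
    alt1 %in% c("A", "C", "G", "T")
  if (any(!keep))
    warning(sum(!keep), " non-bi-allelic/non-SNV VCF record(s) dropped")
  info <- VariantAnnotation::info(vcf)
  getf <- function(key) {
    if (key %in% colnames(info)) as.numeric(info[[key]])
    else rep(NA_real_, length(ref))
  }
  rrdf <- as.data.frame(rr)
  dt <- data.table::data.table(
    chrom = as.character(rrdf$seqnames),
    pos = as.integer(rrdf$start),
    id = names(rr) %||% rep(".", length(rr)),
    ref = ref, alt = alt1,
    qual = as.numeric(VariantAnnotation::qual(vcf)),
    mq = getf("MQ"), qd = getf("QD"), fs = getf("FS"))[keep]
  dt[, snv_id := .snv_id(chrom, pos, ref, alt)]
  if (!is.null(annotation)) {
    ann <- if (is.character(annotation)) data.table::fread(annotation)
           else data.table::as.data.table(annotation)
    dt[ann, on = "snv_id", `:=`(gene = i.gene, category = i.category)]
  }
  data.table::setorderv(dt, c("chrom", "pos"))
  dt[]
}

#' Re-emit a set of SNVs as a VCF
#'
#' Writes a minimal VCF v4.2 carrying the QUAL and MQ/QD/FS fields of the
#' given SNV table, e.g. the survivors of \code{\link{select_het_snvs}}.
#'
#' @param snvs SNV table as returned by \code{\link{read_snv_vcf}}.
#' @param path output file.
#' @param contig_lengths optional named vector of contig lengths for the
#'   header; contigs default to length-less declarations.
#' @return the path, invisibly.
#' @export
write_snv_vcf <- function(snvs, path, contig_lengths = NULL) {
  snvs <- data.table::as.data.table(snvs)
  contigs <- unique(snvs$chrom)
  ctg <- if (is.null(contig_lengths)) {
    sprintf("##contig=<ID=%s>", contigs)
  } else {
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=scvaf %s", as.character(utils::packageVersion("scvaf"))),
    ctg,
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred strand bias\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  s <- snvs[order(chrom, pos)]
  fmt <- function(x) ifelse(is.na(x), ".", sprintf("%.3f", x))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\t.\tMQ=%s;QD=%s;FS=%s",
                  s$chrom, s$pos,
                  if ("id" %in% names(s)) s$id else s$snv_id,
                  s$ref, s$alt, fmt(s$qual), fmt(s$mq), fmt(s$qd), fmt(s$fs))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a gene-by-cell MatrixMarket count matrix
#'
#' Expects \code{matrix.mtx}, \code{features.tsv} (gene names, first column)
#' and \code{barcodes.tsv} in \code{dir}, the layout emitted by
#' \code{\link{simulate_dataset}} and by common cell-ranger-style tools
#' (uncompressed).
#'
#' @param dir directory containing the three files.
#' @return a \code{dgCMatrix} with gene rownames and barcode colnames.
#' @export
read_counts_mtx <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  feat <- file.path(dir, "features.tsv")
  bc <- file.path(dir, "barcodes.tsv")
  for (f in c(mtx, feat, bc))
    if (!file.exists(f)) .stop_data("matrix input missing: ", f)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  features <- data.table::fread(feat, header = FALSE)[[1]]
  barcodes <- data.table::fread(bc, header = FALSE)[[1]]
  if (length(features) != nrow(m) || length(barcodes) != ncol(m))
    .stop_data("features/barcodes do not match matrix dimensions")
  dimnames(m) <- list(features, barcodes)
  m
}
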