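# Barcoded pileup with exact-UMI deduplication.
#
# Coordinates: SNV positions arrive 1-based (VCF convention) and stay 1-based
# throughout Rsamtools, whose ranges are 1-based closed; no conversion is
# needed on this path.

# Map a reference position to the query (read) position for each alignment.
# Returns NA where the position falls in a deletion/refskip or outside the
# aligned span.  Fast path for pure-match CIGARs; general path walks the
# CIGAR ranges in reference and query space.
.query_pos <- function(cigar, start, refpos) {
  out <- rep(NA_integer_, length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  if (any(simple)) {
    w <- as.integer(sub("M$", "", cigar[simple]))
    qp <- refpos[simple] - start[simple] + 1L
    qp[qp < 1L | qp > w] <- NA_integer_
    out[simple] <- qp
  }
  gen <- which(!simple)
  if (length(gen)) {
    ops <- GenomicAlignments::explodeCigarOps(cigar[gen])
    rref <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar[gen], pos = start[gen])
    rqry <- GenomicAlignments::cigarRangesAlongQuerySpace(cigar[gen])
    for (k in seq_along(gen)) {
      i <- gen[k]
      op <- ops[[k]]
      rs <- IRanges::start(rref[[k]]); re <- IRanges::end(rref[[k]])
      qs <- IRanges::start(rqry[[k]])
      hit <- which(op %in% c("M", "=", "X") &
                     rs <= refpos[i] & refpos[i] <= re)
      if (length(hit) == 1L)
        out[i] <- qs[hit] + (refpos[i] - rs[hit])
    }
  }
  out
}

# Shared dedup kernel: one row per distinct `by`-group + UMI, keeping the
# highest mapq, ties broken by (pos, qname) ascending in C locale.
.dedup_dt <- function(dt, by = character(0)) {
  cols <- c(by, "umi", "mapq", "pos", "qname")
  stopifnot(all(cols %in% names(dt)))
  ord <- data.table::copy(dt)
  data.table::setorderv(ord, c(by, "umi", "mapq", "pos", "qname"),
                        order = c(rep(1L, length(by) + 1L), -1L, 1L, 1L))
  unique(ord, by = c(by, "umi"))
}

#' Deduplicate UMI-tagged reads at one locus for one cell
#'
#' Groups reads by exact UMI string and keeps, per UMI, the read with the
#' highest mapping quality; ties are broken deterministically by (alignment
#' position, query name), ascending.  This is the per-molecule collapse
#' applied inside \code{\link{count_alleles}}, exposed for direct use.
#'
#' @param reads data.frame with at least \code{umi}, \code{mapq}, \code{pos},
#'   \code{qname}; extra columns (e.g. the base call) are carried through.
#' @return one surviving row per distinct UMI, ordered by UMI.  Empty input
#'   gives an empty table.
#' @export
dedup_umis <- function(reads) {
  reads <- data.table::as.data.table(reads)
  if (nrow(reads) == 0L) return(reads)
  .dedup_dt(reads)[]
}

#' Count reference and variant molecules per cell at SNV loci
#'
#' Performs a barcoded pileup at each SNV position of a coordinate-sorted,
#' CB/UB-tagged alignment (SAM or BAM).  Reads lacking a CB or UB tag, below
#' the mapping/base-quality thresholds, or (when \code{honor_wasp_tag})
#' carrying an allele-mapping-bias verdict \code{vW != 1} are discarded.
#' Surviving reads are grouped per cell and collapsed to unique molecules by
#' exact UMI (\code{\link{dedup_umis}}); each molecule contributes one count
#' to \code{n_ref}, \code{n_var} or \code{n_other} according to its base at
#' the position.  A base of N counts as other; deletions, reference skips and
#' clipped-over positions contribute nothing.
#'
#' @param alignment path to a SAM or BAM file (converted/sorted/indexed in a
#'   scratch directory as needed).
#' @param snvs SNV table with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} (e.g. from \code{\link{read_snv_vcf}}); a \code{snv_id}
#'   column is added if absent.
#' @param barcode_whitelist optional character vector; cells outside it are
#'   dropped.
#' @param min_base_qual minimum Phred base quality at the SNV position.
#' @param min_map_qual minimum mapping quality (applied before dedup).
#' @param honor_wasp_tag drop reads whose \code{vW} tag is present and not 1.
#' @return data.table (cell_barcode, snv_id, n_ref, n_var, n_other), one row
#'   per (cell, SNV) with at least one surviving molecule, ordered by
#'   (snv_id, cell_barcode).
#' @export
count_alleles <- function(alignment, snvs, barcode_whitelist = NULL,
                          min_base_qual = 20L, min_map_qual = 30L,
                          honor_wasp_tag = TRUE) {
  snvs <- data.table::as.data.table(snvs)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(snvs)))
  if (!"snv_id" %in% names(snvs))
    snvs[, snv_id := .snv_id(chrom, pos, ref, alt)]
  data.table::setorderv(snvs, c("chrom", "pos"))

  bam <- .ensure_bam(alignment)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing_ctg <- setdiff(unique(snvs$chrom), names(hdr))
  if (length(missing_ctg))
    .stop_data("contig(s) absent from alignment header: ",
               paste(missing_ctg, collapse = ", "))

  gr <- GenomicRanges::GRanges(snvs$chrom,
                               IRanges::IRanges(snvs$pos, snvs$pos))
  param <- Rsamtools::ScanBamParam(
    which = gr,
    what = c("qname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("CB", "UB", "vW"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)

  piles <- lapply(seq_along(res), function(i) {
    r <- res[[i]]
    n <- length(r$qname)
    if (n == 0L) return(NULL)
    tag_or_na <- function(x, template)
      if (is.null(x)) rep(template, n) else x
    data.table::data.table(
      snv_idx = i, qname = r$qname, pos = r$pos, mapq = r$mapq,
      cigar = r$cigar, seq_str = as.character(r$seq),
      qual_str = as.character(r$qual),
      cb = tag_or_na(r$tag$CB, NA_character_),
      umi = tag_or_na(r$tag$UB, NA_character_),
      vW = tag_or_na(r$tag$vW, NA_integer_))
  })
  dt <- data.table::rbindlist(piles)
  empty <- data.table::data.table(cell_barcode = character(0),
                                  snv_id = character(0), n_ref = integer(0),
                                  n_var = integer(0), n_other = integer(0))
  if (nrow(dt) == 0L) return(empty)

  dt <- dt[!is.na(cb) & !is.na(umi)]
  dt <- dt[mapq >= min_map_qual]
  if (honor_wasp_tag) dt <- dt[is.na(vW) | vW == 1L]
  if (!is.null(barcode_whitelist)) dt <- dt[cb %in% barcode_whitelist]
  if (nrow(dt) == 0L) return(empty)

  dt[, qpos := .query_pos(cigar, pos, snvs$pos[snv_idx])]
  dt <- dt[!is.na(qpos)]
  if (nrow(dt) == 0L) return(empty)
  dt[, base := substr(seq_str, qpos, qpos)]
  dt[, bqual := .phred_to_int(substr(qual_str, qpos, qpos))]
  dt <- dt[bqual >= min_base_qual & base %in% c("A", "C", "G", "T", "N")]
  if (nrow(dt) == 0L) return(empty)

  mol <- .dedup_dt(dt, by = c("snv_idx", "cb"))
  mol[, allele := data.table::fifelse(
    base == snvs$ref[snv_idx], "ref",
    data.table::fifelse(base == snvs$alt[snv_idx], "var", "other"))]
  out <- mol[, .(n_ref = sum(allele == "ref"),
                 n_var = sum(allele == "var"),
                 n_other = sum(allele == "other")),
             by = .(cell_barcode = cb, snv_idx)]
  out[, snv_id := snvs$snv_id[snv_idx]]
  out[, snv_idx := NULL]
  data.table::setcolorder(out, c("cell_barcode", "snv_id",
                                 "n_ref", "n_var", "n_other"))
  data.table::setorderv(out, c("snv_id", "cell_barcode"))
  out[]
}

#' Pool per-cell allele counts across cells
#'
#' Column sums of the deduplicated molecule counts per SNV, the quantity on
#' which pooled heterozygosity (at least 50 molecules per allele) is judged.
#'
#' @param counts allele-count table from \code{\link{count_alleles}}.
#' @return data.table (snv_id, N_ref, N_var, N_other); empty in, empty out.
#' @export
pool_counts <- function(counts) {
  counts <- .check_counts(counts)
  if (nrow(counts) == 0L)
    return(data.table::data.table(snv_id = character(0), N_ref = integer(0),
                                  N_var = integer(0), N_other = integer(0)))
  out <- counts[, .(N_ref = sum(n_ref), N_var = sum(n_var),
                    N_other = sum(n_other)), by = snv_id]
  data.table::setorderv(out, "snv_id")
  out[]
}
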