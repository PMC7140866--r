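# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.msg <- function(...) message("[scvaf] ", ...)

# n random DNA strings of the given length
.rand_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n, ncol = len)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Random DNA tags, unique within the groups given by `group`.
# Collisions are resampled; with |alphabet|^len >> group sizes this
# terminates almost immediately.
.rand_dna_unique <- function(group, len) {
  n <- length(group)
  tags <- .rand_dna(n, len)
  repeat {
    dup <- duplicated(paste(group, tags, sep = "\r"))
    if (!any(dup)) break
    tags[dup] <- .rand_dna(sum(dup), len)
  }
  tags
}

# Phred+33 ASCII -> integer base qualities, one character per element
.phred_to_int <- function(chars) {
  if (length(chars) == 0L) return(integer(0))
  as.integer(charToRaw(paste(chars, collapse = ""))) - 33L
}

.snv_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = "_")
}

.write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, eol = "\n",
                     logical01 = FALSE, na = "NA")
  invisible(path)
}

.stop_config <- function(...) {
  stop(structure(class = c("scvaf_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.stop_data <- function(...) {
  stop(structure(class = c("scvaf_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Columns every allele-count table must carry
.check_counts <- function(counts) {
  counts <- data.table::as.data.table(counts)
  need <- c("cell_barcode", "snv_id", "n_ref", "n_var")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    .stop_data("count table missing column(s): ", paste(miss, collapse = ", "))
  if (!"n_other" %in% names(counts)) counts[, n_other := 0L]
  counts
}
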