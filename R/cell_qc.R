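# Cell quality control on the raw gene-by-cell count matrix.

#' Flag low-quality cells in a gene-by-cell count matrix
#'
#' A cell passes QC when it has at least \code{min_genes} detected genes
#' (count > 0) and a mitochondrial percentage of total raw counts at most
#' \code{max_pct_mito} (defaults mirror the common scRNA-seq rule: fail on
#' < 3000 detected genes or > 6\% mitochondrial expression; the boundary
#' values 3000 and 6.0 pass).  Percentages are computed on raw counts — the
#' rule needs no normalisation.  A cell with zero total counts gets
#' \code{pct_mito = 0} and fails on the gene count.
#'
#' @param matrix \code{dgCMatrix} (or coercible) with gene rownames and cell
#'   barcode colnames.
#' @param mito_genes explicit character vector of mitochondrial gene names;
#'   must be a subset of the rownames.  If NULL, genes are matched by
#'   \code{mito_prefix}.
#' @param mito_prefix prefix identifying mitochondrial genes when
#'   \code{mito_genes} is NULL.
#' @param min_genes minimum detected genes.
#' @param max_pct_mito maximum mitochondrial percentage (0-100).
#' @return data.table (barcode, n_genes_detected, pct_mito, pass_qc).
#' @export
qc_cells <- function(matrix, mito_genes = NULL, mito_prefix = "MT-",
                     min_genes = 3000L, max_pct_mito = 6.0) {
  m <- methods::as(matrix, "CsparseMatrix")
  if (nrow(m) == 0L || ncol(m) == 0L)
    .stop_data("empty count matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    .stop_data("count matrix must carry gene rownames and barcode colnames")
  if (is.null(mito_genes)) {
    mito_genes <- rownames(m)[startsWith(rownames(m), mito_prefix)]
  } else if (!all(mito_genes %in% rownames(m))) {
    .stop_data("mito_genes not all present in matrix rownames")
  }
  detected <- Matrix::colSums(m > 0)
  total <- Matrix::colSums(m)
  mito <- if (length(mito_genes))
    Matrix::colSums(m[rownames(m) %in% mito_genes, , drop = FALSE])
  else rep(0, ncol(m))
  pct <- ifelse(total > 0, 100 * mito / total, 0)
  data.table::data.table(
    barcode = colnames(m),
    n_genes_detected = as.integer(detected),
    pct_mito = as.numeric(pct),
    pass_qc = detected >= min_genes & pct <= max_pct_mito)
}
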