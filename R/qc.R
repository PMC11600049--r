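# Cell-level quality control, log-normalisation and covariate regression.
#
# Boundary semantics follow a literal reading of the filtering rules:
# "fewer than 200" / "more than 5000" detected genes, "exceeding 30 000"
# UMIs and "over 30%" mitochondrial content are all strict, so cells at
# exactly 200 / 5000 genes, 30 000 UMIs or 30.0% mito are kept.

#' Default QC thresholds
#'
#' @param min_genes,max_genes Inclusive bounds on the number of detected
#'   genes per cell.
#' @param max_umi Inclusive upper bound on total UMIs per cell.
#' @param max_pct_mito Inclusive upper bound on mitochondrial percentage.
#' @return A `QCThresholds` list.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 5000,
                          max_umi = 30000, max_pct_mito = 30) {
  if (min_genes >= max_genes) stopf("min_genes must be < max_genes")
  if (min_genes < 0 || max_umi <= 0 || max_pct_mito <= 0) {
    stopf("thresholds must be positive")
  }
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_umi = max_umi, max_pct_mito = max_pct_mito),
            class = "QCThresholds")
}

#' Compute per-cell QC metrics
#'
#' @param dataset An [expression_dataset()].
#' @param mito_prefix Gene-symbol prefix identifying mitochondrial genes.
#' @return Data frame with one row per cell: cell_id, n_genes (genes with
#'   count > 0), n_umi (total counts), pct_mito (0-100; 0 for empty cells).
#' @export
compute_cell_qc <- function(dataset, mito_prefix = "MT-") {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (!nzchar(mito_prefix)) stopf("mito_prefix must be non-empty")
  counts <- dataset$counts
  n_umi <- Matrix::rowSums(counts)
  n_genes <- Matrix::rowSums(counts > 0)
  mito <- startsWith(dataset$gene_ids, mito_prefix)
  mito_umi <- if (any(mito)) Matrix::rowSums(counts[, mito, drop = FALSE]) else 0
  pct_mito <- ifelse(n_umi > 0, 100 * mito_umi / n_umi, 0)
  data.frame(cell_id = dataset$cell_ids, n_genes = as.integer(n_genes),
             n_umi = as.integer(n_umi), pct_mito = as.numeric(pct_mito),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply QC filters to per-cell metrics
#'
#' A cell is kept iff `min_genes <= n_genes <= max_genes`,
#' `n_umi <= max_umi` and `pct_mito <= max_pct_mito` (all bounds inclusive).
#'
#' @param qc Output of [compute_cell_qc()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `kept` (cell ids passing every rule) and `removed`
#'   (named counts of cells failing each rule; a cell can fail several).
#' @export
apply_qc_filters <- function(qc, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "QCThresholds"))
  fail_low_genes <- qc$n_genes < thresholds$min_genes
  fail_high_genes <- qc$n_genes > thresholds$max_genes
  fail_umi <- qc$n_umi > thresholds$max_umi
  fail_mito <- qc$pct_mito > thresholds$max_pct_mito
  keep <- !(fail_low_genes | fail_high_genes | fail_umi | fail_mito)
  list(kept = qc$cell_id[keep],
       removed = c(low_genes = sum(fail_low_genes),
                   high_genes = sum(fail_high_genes),
                   high_umi = sum(fail_umi),
                   high_mito = sum(fail_mito)))
}

#' Library-size log-normalise a count matrix
#'
#' `norm[c, g] = ln(1 + scale_factor * counts[c, g] / n_umi[c])`; rows with
#' zero total counts map to zeros.
#'
#' @param dataset An [expression_dataset()].
#' @param scale_factor Target library size (default 10 000).
#' @return The dataset with its `norm` slot filled (sparse, cells x genes).
#' @export
normalize_log1p <- function(dataset, scale_factor = 10000) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (scale_factor <= 0) stopf("scale_factor must be positive")
  counts <- dataset$counts
  n_umi <- Matrix::rowSums(counts)
  inv <- ifelse(n_umi > 0, scale_factor / n_umi, 0)
  norm <- Matrix::Diagonal(x = inv) %*% counts
  norm@x <- log1p(norm@x)
  dataset$norm <- methods::as(norm, "CsparseMatrix")
  dimnames(dataset$norm) <- dimnames(counts)
  dataset
}

#' Regress covariates out of a normalised expression matrix
#'
#' Per gene, fits ordinary least squares on the covariates plus an
#' intercept and replaces values with residual + original gene mean, so
#' gene means are preserved. Used e.g. to remove cell-cycle module scores.
#'
#' @param norm Numeric matrix, cells x genes.
#' @param covariates Numeric matrix or data frame, one row per cell.
#' @return Dense residualised matrix of the same shape.
#' @export
regress_out <- function(norm, covariates) {
  norm <- as.matrix(norm)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != nrow(norm)) {
    stopf("covariates have %d rows for %d cells", nrow(covariates), nrow(norm))
  }
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- sprintf("cov%d", seq_len(ncol(covariates)))
  }
  X <- cbind(`(Intercept)` = 1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("covariate matrix is rank-deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  resid <- qr.resid(qx, norm)
  means <- colMeans(norm)
  out <- sweep(resid, 2, means, `+`)
  dimnames(out) <- dimnames(norm)
  out
}
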