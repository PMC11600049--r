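# Marker detection and annotation: the Wilcoxon rank-sum / AUC engine,
# one-vs-rest marker discovery with Bonferroni correction and the
# pct >= 0.25 / adjusted p < 0.05 / log2FC > 0.25 retention rule,
# score-based cluster annotation against a reference marker panel,
# composition tables, top-N signatures and two-gene quadrant classification.

# Rank-sum machinery -----------------------------------------------------

# Two-sided Mann-Whitney p for a single gene. Exact enumeration over all
# group assignments when the pooled size is <= 12 (valid under ties because
# U is symmetric around n1*n2/2 across assignments); otherwise the
# tie-corrected normal approximation without continuity correction.
rank_sum_p <- function(ranks, n_in, U) {
  N <- length(ranks)
  n_out <- N - n_in
  mu <- n_in * n_out / 2
  if (N <= 12) {
    combos <- utils::combn(N, n_in)
    Us <- colSums(matrix(ranks[combos], nrow = n_in)) - n_in * (n_in + 1) / 2
    return(mean(abs(Us - mu) >= abs(U - mu) - 1e-9))
  }
  ties <- table(ranks)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n_in * n_out / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (U - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon rank-sum / AUC differential expression between two cell sets
#'
#' For every gene: AUC = U / (n_in * n_out) with ties counted half (average
#' ranks); two-sided p from the tie-corrected normal approximation (exact
#' enumeration when n_in + n_out <= 12); log2FC on back-transformed means,
#' `log2((mean(exp(x_in) - 1) + 1) / (mean(exp(x_out) - 1) + 1))`;
#' detection fractions are the proportions of cells with expression > 0.
#'
#' @param norm Normalised expression matrix (cells x genes) with cell ids as
#'   row names, e.g. the `norm` slot of a dataset after [normalize_log1p()].
#' @param in_cells,out_cells Disjoint non-empty vectors of cell ids (or row
#'   indices).
#' @return Data frame with one row per gene: gene, auc, log2fc, p, pct_in,
#'   pct_out.
#' @export
wilcoxon_auc <- function(norm, in_cells, out_cells) {
  if (length(in_cells) == 0 || length(out_cells) == 0) {
    stopf("both cell groups must be non-empty")
  }
  if (is.character(in_cells) || is.character(out_cells)) {
    if (length(intersect(in_cells, out_cells))) stopf("cell groups overlap")
  } else if (length(intersect(in_cells, out_cells))) {
    stopf("cell groups overlap")
  }
  x_in <- as.matrix(norm[in_cells, , drop = FALSE])
  x_out <- as.matrix(norm[out_cells, , drop = FALSE])
  n_in <- nrow(x_in); n_out <- nrow(x_out)
  genes <- colnames(norm) %||% sprintf("gene%d", seq_len(ncol(norm)))
  auc <- numeric(length(genes)); p <- numeric(length(genes))
  for (g in seq_along(genes)) {
    pooled <- c(x_in[, g], x_out[, g])
    r <- rank(pooled)
    U <- sum(r[seq_len(n_in)]) - n_in * (n_in + 1) / 2
    auc[g] <- U / (n_in * n_out)
    p[g] <- rank_sum_p(r, n_in, U)
  }
  log2fc <- log2((colMeans(expm1(x_in)) + 1) / (colMeans(expm1(x_out)) + 1))
  data.frame(gene = genes, auc = auc, log2fc = as.numeric(log2fc), p = p,
             pct_in = colMeans(x_in > 0), pct_out = colMeans(x_out > 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-vs-rest marker discovery across clusters
#'
#' Runs [wilcoxon_auc()] for every cluster against all other cells,
#' Bonferroni-adjusts p over the genes tested per cluster, and retains
#' genes detected in at least 25% of the cluster with adjusted p < 0.05
#' and log2FC > 0.25.
#'
#' @param norm Normalised expression matrix (cells x genes).
#' @param clusters Cluster label per cell (row).
#' @param min_pct,max_p_adj,min_log2fc Retention thresholds.
#' @return Data frame of retained markers: cluster, gene, auc, log2fc, p,
#'   p_adj, pct_in, pct_out. Clusters with fewer than 3 cells are skipped
#'   with a warning.
#' @export
find_all_markers <- function(norm, clusters, min_pct = 0.25,
                             max_p_adj = 0.05, min_log2fc = 0.25) {
  clusters <- as.character(clusters)
  if (length(clusters) != nrow(norm)) {
    stopf("clusters has %d labels for %d cells", length(clusters), nrow(norm))
  }
  if (length(unique(clusters)) < 2) stopf("need at least 2 clusters")
  out <- list()
  for (cl in sort(unique(clusters))) {
    idx_in <- which(clusters == cl)
    if (length(idx_in) < 3) {
      warnf("cluster '%s' has fewer than 3 cells; skipped", cl)
      next
    }
    stats <- wilcoxon_auc(norm, idx_in, which(clusters != cl))
    stats$p_adj <- pmin(1, stats$p * nrow(stats))  # Bonferroni over genes
    keep <- stats$pct_in >= min_pct & stats$p_adj < max_p_adj &
      stats$log2fc > min_log2fc
    if (any(keep)) {
      res <- stats[keep, , drop = FALSE]
      res$cluster <- cl
      out[[cl]] <- res
    }
  }
  if (!length(out)) {
    return(data.frame(cluster = character(0), gene = character(0),
                      auc = numeric(0), log2fc = numeric(0), p = numeric(0),
                      p_adj = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("cluster", "gene", "auc", "log2fc", "p", "p_adj", "pct_in",
          "pct_out")]
}

#' Reference marker panel for major cell lineages
#'
#' The canonical lineage markers used for annotation: T/NK (CD3D, CD3E,
#' CD3G, NKG7), plasma (JCHAIN, IGKC, IGHG1), B (CD79A, MS4A1, CD19),
#' myeloid (LYZ, CD14, SPP1), CAF (DCN, LUM, COL1A1), epithelial (EPCAM,
#' KRT8, CAPS), mast (KIT, CPA3, MS4A2), endothelial (VWF, PECAM1, CALCRL).
#'
#' @return Named list mapping cell type to marker gene vector.
#' @export
marker_reference <- function() {
  list(
    `T/NK` = c("CD3D", "CD3E", "CD3G", "NKG7"),
    Plasma = c("JCHAIN", "IGKC", "IGHG1"),
    B = c("CD79A", "MS4A1", "CD19"),
    Myeloid = c("LYZ", "CD14", "SPP1"),
    CAF = c("DCN", "LUM", "COL1A1"),
    Epithelial = c("EPCAM", "KRT8", "CAPS"),
    Mast = c("KIT", "CPA3", "MS4A2"),
    Endothelial = c("VWF", "PECAM1", "CALCRL")
  )
}

#' Annotate clusters against a reference marker panel
#'
#' Scores each (cluster, cell type) pair as the mean normalised expression
#' of the type's marker genes over the cluster's cells and assigns the
#' argmax; clusters whose top two scores differ by less than 10% relative
#' to the top score are flagged ambiguous.
#'
#' @param norm Normalised expression matrix (cells x genes).
#' @param clusters Cluster label per cell.
#' @param reference Named list of marker genes per type (default
#'   [marker_reference()]). Reference genes absent from the matrix are
#'   dropped with a warning; if none remain, an error is raised.
#' @return Data frame: cluster, cell_type, score, margin, ambiguous.
#' @export
annotate_clusters <- function(norm, clusters, reference = marker_reference()) {
  genes <- colnames(norm)
  present <- lapply(reference, intersect, genes)
  missing <- setdiff(unlist(reference), genes)
  if (length(missing)) {
    warnf("%d reference gene(s) absent from the matrix: %s", length(missing),
          paste(utils::head(missing, 8), collapse = ", "))
  }
  present <- present[vapply(present, length, integer(1)) > 0]
  if (!length(present)) stopf("no reference marker genes present in the matrix")
  clusters <- as.character(clusters)
  out <- lapply(sort(unique(clusters)), function(cl) {
    rows <- clusters == cl
    scores <- vapply(present, function(gs) {
      mean(as.matrix(norm[rows, gs, drop = FALSE]))
    }, numeric(1))
    ord <- order(scores, decreasing = TRUE)
    top <- scores[ord[1]]
    second <- if (length(scores) > 1) scores[ord[2]] else -Inf
    margin <- top - second
    ambiguous <- is.finite(second) &&
      (top == second || margin < 0.10 * abs(top))
    data.frame(cluster = cl, cell_type = names(present)[ord[1]],
               score = top, margin = margin, ambiguous = ambiguous,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cell-type composition percentages
#'
#' Either tabulates per-cell metadata within strata, or converts a named
#' count vector directly. Percentages are reported to 2 decimals and sum to
#' 100 within each stratum up to rounding.
#'
#' @param x Per-cell metadata data frame with a `cell_type` (or `cluster`)
#'   column, or a named numeric vector of per-type cell counts.
#' @param by Stratifying metadata column ("group" or "sample_id") when `x`
#'   is a data frame.
#' @return Data frame: stratum, cell_type, n, pct.
#' @export
composition_table <- function(x, by = "group") {
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
    total <- sum(counts)
    if (total == 0) stopf("all counts are zero")
    return(data.frame(stratum = "all", cell_type = names(counts),
                      n = as.numeric(counts),
                      pct = round(100 * counts / total, 2),
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  meta <- as.data.frame(x, stringsAsFactors = FALSE)
  type_col <- if ("cell_type" %in% names(meta)) "cell_type" else "cluster"
  if (!by %in% names(meta)) stopf("no metadata column '%s'", by)
  out <- list()
  for (s in unique(meta[[by]])) {
    sub <- meta[meta[[by]] == s, , drop = FALSE]
    if (!nrow(sub)) {
      warnf("stratum '%s' is empty; omitted", s)
      next
    }
    tab <- table(sub[[type_col]])
    out[[s]] <- data.frame(stratum = s, cell_type = names(tab),
                           n = as.numeric(tab),
                           pct = round(100 * as.numeric(tab) / nrow(sub), 2),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top-N marker signature for one cluster
#'
#' Genes sorted by log2FC descending; ties broken by smaller p, then
#' lexicographic gene id. Used to build the 10-gene survival signatures.
#'
#' @param markers [find_all_markers()] rows for a single cluster.
#' @param n Signature size (default 10).
#' @return Character vector of up to `n` genes (all, with a warning, if
#'   fewer are available).
#' @export
top_n_signature <- function(markers, n = 10) {
  if (n == 0) return(character(0))
  ord <- order(-markers$log2fc, markers$p, markers$gene)
  genes <- markers$gene[ord]
  if (length(genes) < n) {
    warnf("only %d markers available for a top-%d signature", length(genes), n)
    return(genes)
  }
  genes[seq_len(n)]
}

#' Classify cells into expression quadrants of two genes
#'
#' Positivity means raw count > 0. The default axes (CXCL9, SPP1) give the
#' four macrophage polarity quadrants.
#'
#' @param dataset An [expression_dataset()].
#' @param cells Cell ids to classify (default: all).
#' @param gene_x,gene_y Quadrant axis genes.
#' @param clusters Optional cluster label per classified cell for
#'   per-cluster fractions; default uses `meta$cluster`.
#' @return List with `cells` (cell_id, label) and `fractions` (cluster,
#'   label, fraction; fractions sum to 1 within a cluster).
#' @export
classify_quadrants <- function(dataset, cells = NULL, gene_x = "CXCL9",
                               gene_y = "SPP1", clusters = NULL) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  for (g in c(gene_x, gene_y)) {
    if (!g %in% dataset$gene_ids) stopf("gene '%s' absent from dataset", g)
  }
  cells <- cells %||% dataset$cell_ids
  x_pos <- as.vector(dataset$counts[cells, gene_x] > 0)
  y_pos <- as.vector(dataset$counts[cells, gene_y] > 0)
  label <- paste0(gene_x, ifelse(x_pos, "+", "-"),
                  gene_y, ifelse(y_pos, "+", "-"))
  clusters <- clusters %||% dataset$meta[cells, "cluster"]
  per_cell <- data.frame(cell_id = cells, label = label,
                         stringsAsFactors = FALSE)
  levels_ <- paste0(gene_x, c("-", "-", "+", "+"),
                    gene_y, c("-", "+", "-", "+"))
  fr <- do.call(rbind, lapply(unique(clusters), function(cl) {
    sub <- label[clusters == cl]
    data.frame(cluster = cl, label = levels_,
               fraction = as.numeric(table(factor(sub, levels = levels_))) /
                 length(sub),
               stringsAsFactors = FALSE)
  }))
  rownames(fr) <- NULL
  list(cells = per_cell, fractions = fr)
}
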