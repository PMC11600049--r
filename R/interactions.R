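# Ligand-receptor interaction scoring and filtering. The communication
# probability is a documented simplified score (Hill-saturated product of
# trimmed means); the retention filter — ligand and receptor detected in
# over 10% of sender and receiver cells, ligand log2FC > 0.1, adjusted
# p < 0.05 — is applied verbatim.

#' Fraction of cells expressing a gene
#'
#' "Expressed" means raw count > 0.
#'
#' @param dataset An [expression_dataset()] (or a counts matrix with cell
#'   ids as row names).
#' @param cells Non-empty vector of cell ids.
#' @param gene Gene symbol.
#' @return Fraction in [0, 1].
#' @export
expression_fraction <- function(dataset, cells, gene) {
  counts <- if (inherits(dataset, "ExpressionDataset")) dataset$counts else dataset
  if (!gene %in% colnames(counts)) stopf("gene '%s' absent", gene)
  if (!length(cells)) stopf("empty cell set")
  mean(counts[cells, gene] > 0)
}

trimmed_mean <- function(x) mean(x, trim = 0.25)

#' Simplified ligand-receptor communication probability
#'
#' L = 25%-trimmed mean of ligand normalised expression over sender cells;
#' R = geometric mean over receptor subunits of their trimmed means over
#' receiver cells (any zero subunit mean gives R = 0); probability =
#' L*R / (K_h + L*R) with half-saturation K_h = 0.5.
#'
#' @param norm Normalised expression matrix (cells x genes).
#' @param sender_cells,receiver_cells Cell id vectors.
#' @param pair One row of an [lr_database()] (needs `ligand` and
#'   `receptor_subunits`).
#' @param k_h Half-saturation constant.
#' @return Probability in [0, 1).
#' @export
communication_probability <- function(norm, sender_cells, receiver_cells,
                                      pair, k_h = 0.5) {
  ligand <- pair$ligand
  subunits <- if (is.list(pair$receptor_subunits)) pair$receptor_subunits[[1]]
    else pair$receptor_subunits
  missing <- setdiff(c(ligand, subunits), colnames(norm))
  if (length(missing)) {
    stopf("gene(s) absent from matrix: %s", paste(missing, collapse = ", "))
  }
  L <- trimmed_mean(as.numeric(norm[sender_cells, ligand]))
  sub_means <- vapply(subunits, function(g) {
    trimmed_mean(as.numeric(norm[receiver_cells, g]))
  }, numeric(1))
  R <- if (any(sub_means == 0)) 0 else exp(mean(log(sub_means)))
  lr <- L * R
  lr / (k_h + lr)
}

#' Permutation test and retention filter for ligand-receptor pairs
#'
#' For each pair, the observed communication probability from sender to
#' receiver cluster is compared to a null built by shuffling cluster labels
#' among the union of sender and receiver cells
#' (`p = (1 + #null >= observed) / (1 + n_perm)`), BH-adjusted across
#' pairs. The ligand's log2FC is computed sender-vs-all-other-cells with
#' the marker engine's formula. A pair is retained iff both detection
#' fractions exceed 0.10, ligand log2FC > 0.1 and adjusted p < 0.05.
#'
#' @param dataset A normalised [expression_dataset()] (run
#'   [normalize_log1p()] first).
#' @param lr_db An [lr_database()].
#' @param sender,receiver Cluster labels in `meta$cluster` (each needs at
#'   least 3 cells, otherwise the test is skipped with a warning).
#' @param n_perm Number of label permutations (>= 50).
#' @param seed Integer seed.
#' @return Data frame: pair_name, sender_cluster, receiver_cluster,
#'   probability, p, p_adj, ligand_log2fc, sender_fraction,
#'   receiver_fraction, retained.
#' @export
interaction_test <- function(dataset, lr_db, sender, receiver,
                             n_perm = 100, seed = 1) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (is.null(dataset$norm)) stopf("dataset is not normalised")
  if (n_perm < 50) stopf("n_perm must be >= 50")
  meta <- dataset$meta
  sender_cells <- meta$cell_id[meta$cluster == sender]
  receiver_cells <- meta$cell_id[meta$cluster == receiver]
  if (length(sender_cells) < 3 || length(receiver_cells) < 3) {
    warnf("cluster with fewer than 3 cells; interaction test skipped")
    return(data.frame())
  }
  norm <- dataset$norm
  genes <- colnames(norm)
  usable <- vapply(seq_len(nrow(lr_db)), function(i) {
    all(c(lr_db$ligand[i], lr_db$receptor_subunits[[i]]) %in% genes)
  }, logical(1))
  if (any(!usable)) {
    warnf("%d pair(s) with genes absent from the dataset skipped",
          sum(!usable))
  }
  db <- lr_db[usable, , drop = FALSE]
  if (!nrow(db)) stopf("no usable ligand-receptor pairs")
  other_cells <- setdiff(dataset$cell_ids, sender_cells)

  observed <- vapply(seq_len(nrow(db)), function(i) {
    communication_probability(norm, sender_cells, receiver_cells, db[i, ])
  }, numeric(1))

  pool <- c(sender_cells, receiver_cells)
  n_s <- length(sender_cells)
  with_seed(seed, {
    exceed <- integer(nrow(db))
    for (b in seq_len(n_perm)) {
      perm <- sample(pool)
      ps <- perm[seq_len(n_s)]
      pr <- perm[-seq_len(n_s)]
      null_b <- vapply(seq_len(nrow(db)), function(i) {
        communication_probability(norm, ps, pr, db[i, ])
      }, numeric(1))
      exceed <- exceed + (null_b >= observed)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  p_adj <- bh_adjust(p)

  res <- lapply(seq_len(nrow(db)), function(i) {
    ligand <- db$ligand[i]
    subunits <- db$receptor_subunits[[i]]
    sf <- min(vapply(c(ligand), expression_fraction, numeric(1),
                     dataset = dataset, cells = sender_cells))
    rf <- min(vapply(subunits, expression_fraction, numeric(1),
                     dataset = dataset, cells = receiver_cells))
    lfc <- log2((mean(expm1(as.numeric(norm[sender_cells, ligand]))) + 1) /
                (mean(expm1(as.numeric(norm[other_cells, ligand]))) + 1))
    data.frame(pair_name = db$pair_name[i], sender_cluster = sender,
               receiver_cluster = receiver, probability = observed[i],
               p = p[i], p_adj = p_adj[i], ligand_log2fc = lfc,
               sender_fraction = sf, receiver_fraction = rf,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$retained <- res$sender_fraction > 0.10 & res$receiver_fraction > 0.10 &
    res$ligand_log2fc > 0.1 & res$p_adj < 0.05
  rownames(res) <- NULL
  res
}
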