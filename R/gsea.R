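# Preranked GSEA: AUC-derived ranking metric, the classic weighted
# Kolmogorov-Smirnov running-sum enrichment score, and gene-set permutation
# NES / p / FDR (sets are permuted rather than phenotypes because the
# pipeline consumes preranked lists).

#' Rank genes by AUC for preranked GSEA
#'
#' Metric = AUC - 0.5 (signed, so 0 means no discrimination), sorted
#' descending; ties broken by log2FC descending, then gene id.
#'
#' @param marker_stats [wilcoxon_auc()] output (one row per gene).
#' @return Data frame (gene, metric) in ranking order, class `RankedList`.
#' @export
rank_by_auc <- function(marker_stats) {
  if (anyDuplicated(marker_stats$gene)) {
    stopf("duplicate genes in marker stats")
  }
  metric <- marker_stats$auc - 0.5
  ord <- order(-metric, -marker_stats$log2fc, marker_stats$gene)
  res <- data.frame(gene = marker_stats$gene[ord], metric = metric[ord],
                    stringsAsFactors = FALSE)
  class(res) <- c("RankedList", "data.frame")
  res
}

#' Weighted running-sum enrichment score
#'
#' Walking down the ranked list, hits add `|metric|^weight_p` (normalised
#' by the total over hits) and misses subtract `1/(N - N_hits)`; the
#' enrichment score is the running-sum value of maximal absolute deviation.
#' The leading edge contains the hit genes up to the extremum (from the
#' extremum onward for negative scores). When all hit metrics are zero the
#' hit increments fall back to uniform weights.
#'
#' @param ranked A [rank_by_auc()] result (or data frame with gene, metric
#'   in ranking order).
#' @param gene_set Character vector; must intersect the ranked universe and
#'   not cover it entirely.
#' @param weight_p Metric weighting exponent (default 1).
#' @return List (es, running_sum, leading_edge).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  genes <- ranked$gene
  N <- length(genes)
  hit <- genes %in% gene_set
  n_hits <- sum(hit)
  if (n_hits == 0) stopf("gene set does not intersect the ranked list")
  if (n_hits == N) stopf("gene set covers the whole ranked list")
  w <- abs(ranked$metric)^weight_p
  denom <- sum(w[hit])
  increments <- if (denom > 0) {
    ifelse(hit, w / denom, -1 / (N - n_hits))
  } else {
    ifelse(hit, 1 / n_hits, -1 / (N - n_hits))
  }
  running <- cumsum(increments)
  pos <- which.max(abs(running))
  es <- running[pos]
  leading_edge <- if (es >= 0) genes[hit & seq_len(N) <= pos] else
    genes[hit & seq_len(N) >= pos]
  list(es = es, running_sum = running, leading_edge = leading_edge)
}

#' Permutation NES, p and FDR for a collection of gene sets
#'
#' The null for each set is the enrichment score of random gene sets of the
#' same size drawn from the ranked universe. NES divides the observed score
#' by the mean |null score| of matching sign; p is the matching-sign
#' exceedance fraction (with add-one smoothing); FDR is the standard
#' per-sign ratio-of-tails estimator over the pooled normalised null,
#' capped at 1.
#'
#' @param ranked A [rank_by_auc()] result.
#' @param gene_sets Named list of gene sets (e.g. [read_gmt()] output).
#' @param n_perm Number of null sets per gene set (>= 100).
#' @param seed Integer seed; results are deterministic given it.
#' @param weight_p Passed to [enrichment_score()].
#' @return Data frame: set_name, size, es, nes, p, fdr, and a
#'   `leading_edge` list-column.
#' @export
nes_fdr <- function(ranked, gene_sets, n_perm = 1000, seed = 1,
                    weight_p = 1) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  genes <- ranked$gene
  sets <- lapply(gene_sets, intersect, genes)
  sizes <- vapply(sets, length, integer(1))
  if (any(sizes == 0)) {
    stopf("gene set(s) with empty intersection: %s",
          paste(names(sets)[sizes == 0], collapse = ", "))
  }
  obs <- lapply(sets, function(s) enrichment_score(ranked, s, weight_p))
  es <- vapply(obs, `[[`, numeric(1), "es")
  with_seed(seed, {
    null_by_set <- lapply(sizes, function(k) {
      vapply(seq_len(n_perm), function(i) {
        enrichment_score(ranked, sample(genes, k), weight_p)$es
      }, numeric(1))
    })
  })
  nes <- numeric(length(sets)); p <- numeric(length(sets))
  null_nes_all <- list()
  for (i in seq_along(sets)) {
    null <- null_by_set[[i]]
    same <- if (es[i] >= 0) null[null >= 0] else null[null < 0]
    if (!length(same) || mean(abs(same)) == 0) {
      stopf("degenerate null distribution for set '%s'", names(sets)[i])
    }
    nes[i] <- es[i] / mean(abs(same))
    p[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
    # normalise the whole null of this set by its per-sign means to build
    # the pooled null NES distribution
    pos_mean <- mean(null[null >= 0]); neg_mean <- mean(abs(null[null < 0]))
    null_nes_all[[i]] <- ifelse(null >= 0,
                                if (is.nan(pos_mean) || pos_mean == 0) 0 else
                                  null / pos_mean,
                                if (is.nan(neg_mean) || neg_mean == 0) 0 else
                                  null / neg_mean)
  }
  pooled <- unlist(null_nes_all)
  fdr <- vapply(seq_along(sets), function(i) {
    if (nes[i] >= 0) {
      null_tail <- mean(pooled[pooled >= 0] >= nes[i])
      obs_tail <- mean(nes[nes >= 0] >= nes[i])
    } else {
      null_tail <- mean(pooled[pooled < 0] <= nes[i])
      obs_tail <- mean(nes[nes < 0] <= nes[i])
    }
    if (obs_tail == 0) return(0)
    min(1, null_tail / obs_tail)
  }, numeric(1))
  res <- data.frame(set_name = names(sets), size = sizes, es = es, nes = nes,
                    p = p, fdr = fdr, stringsAsFactors = FALSE)
  res$leading_edge <- lapply(obs, `[[`, "leading_edge")
  rownames(res) <- NULL
  res
}
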