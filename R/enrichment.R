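# Cluster-by-group odds-ratio preference testing: for every (cluster,
# group) combination a 2x2 contingency table of cells is built, Fisher's
# exact test gives the odds ratio and p value, p values are BH-corrected
# jointly across all combinations, and a combination is labelled enriched
# when OR > 1.5 with adjusted p < 0.01 (depleted when OR < 0.5).

#' Build the 2x2 cluster-by-group contingency table
#'
#' a = cells in cluster i and group j; b = cells in cluster i outside group
#' j; c = cells in group j outside cluster i; d = all remaining cells.
#'
#' @param meta Per-cell metadata with `cluster` and `group` columns.
#' @param cluster_i,group_j Labels present in `meta`.
#' @return Named list (a, b, c, d) of class `ContingencyTable`.
#' @export
build_contingency <- function(meta, cluster_i, group_j) {
  if (!cluster_i %in% meta$cluster) stopf("unknown cluster '%s'", cluster_i)
  if (!group_j %in% meta$group) stopf("unknown group '%s'", group_j)
  in_cl <- meta$cluster == cluster_i
  in_gr <- meta$group == group_j
  structure(list(a = sum(in_cl & in_gr), b = sum(in_cl & !in_gr),
                 c = sum(!in_cl & in_gr), d = sum(!in_cl & !in_gr)),
            class = "ContingencyTable")
}

#' Fisher's exact test with sample odds ratio
#'
#' The odds ratio is the cross-product ratio `(a*d)/(b*c)`, with 0.5 added
#' to every cell only when some cell is zero (Haldane-Anscombe). The
#' two-sided p value sums hypergeometric probabilities of all tables (with
#' the observed margins) whose probability does not exceed the observed
#' table's, with a 1e-7 relative tolerance for ties.
#'
#' @param table A [build_contingency()] result or a list/vector with
#'   elements a, b, c, d.
#' @return List `(odds_ratio, p)`.
#' @export
fisher_or <- function(table) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (any(c(a, b, c, d) < 0)) stopf("negative cell in contingency table")
  if (a + b + c + d == 0) stopf("all-zero contingency table")
  if (any(c(a, b, c, d) == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  # hypergeometric support for fixed margins: x = count in cell a
  m <- a + b          # cluster size
  n <- c + d          # out-of-cluster size
  k <- a + c          # group size
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p = min(1, p))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (monotone, capped at 1), validating that
#' inputs lie in (0, 1].
#'
#' @param p_values Numeric vector of p values in (0, 1].
#' @return Adjusted p values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stopf("p values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Odds-ratio preference matrix over all cluster-by-group combinations
#'
#' Fisher OR and p for every combination, BH correction jointly over all
#' combinations, and a preference label: `enriched` iff adjusted p < 0.01
#' and OR > 1.5; `depleted` iff adjusted p < 0.01 and OR < 0.5; else `ns`.
#'
#' @param meta Per-cell metadata with `cluster` and `group` columns. With
#'   `by = "samples"` the counting unit is samples (each sample assigned to
#'   its majority cluster) instead of cells; cells is the default and
#'   matches how composition is tabulated.
#' @param or_hi,or_lo,alpha Label thresholds.
#' @param by Counting unit, `"cells"` (default) or `"samples"`.
#' @return Data frame: cluster, group, a, odds_ratio, p, p_adj, label.
#' @export
or_preference_matrix <- function(meta, or_hi = 1.5, or_lo = 0.5,
                                 alpha = 0.01, by = c("cells", "samples")) {
  by <- match.arg(by)
  if (by == "samples") {
    # one record per (sample, cluster) pseudo-unit to damp pseudo-replication
    tab <- unique(meta[, c("sample_id", "cluster", "group")])
    meta <- tab
  }
  clusters <- sort(unique(meta$cluster))
  groups <- sort(unique(meta$group))
  if (length(clusters) < 2 || length(groups) < 2) {
    stopf("need at least 2 clusters and 2 groups")
  }
  grid <- expand.grid(cluster = clusters, group = groups,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tab <- build_contingency(meta, grid$cluster[i], grid$group[i])
    f <- fisher_or(tab)
    data.frame(cluster = grid$cluster[i], group = grid$group[i], a = tab$a,
               odds_ratio = f$odds_ratio, p = f$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- bh_adjust(res$p)
  res$label <- ifelse(res$p_adj < alpha & res$odds_ratio > or_hi, "enriched",
               ifelse(res$p_adj < alpha & res$odds_ratio < or_lo, "depleted",
                      "ns"))
  rownames(res) <- NULL
  res
}
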