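# CNV scoring and clonal structure: copy-neutral-centered residual
# estimation (a smoothing stand-in for an HMM-based caller), the quadratic
# CNV score, malignant-cell classification at mean + 2 SD of a reference
# population, arm-level event mapping via cytobands, subclone collapsing by
# identical arm-level event sets, and clonal-tree construction with Newick
# output.

#' Construct a validated CNV profile
#'
#' @param residuals Numeric matrix (cells x windows), centered so 0 means
#'   copy-neutral.
#' @param windows Data frame (chrom, start, end), 0-based half-open, in
#'   genomic order (chrom, then start).
#' @param cell_ids Cell identifiers, one per row.
#' @param reference_cell_ids Subset of `cell_ids` used as diploid baseline.
#' @return An object of class `CNVProfile`.
#' @export
cnv_profile <- function(residuals, windows, cell_ids, reference_cell_ids) {
  residuals <- as.matrix(residuals)
  windows <- as.data.frame(windows, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(windows)))
  if (nrow(residuals) != length(cell_ids)) {
    stopf("residuals have %d rows for %d cells", nrow(residuals),
          length(cell_ids))
  }
  if (ncol(residuals) != nrow(windows)) {
    stopf("residuals have %d columns for %d windows", ncol(residuals),
          nrow(windows))
  }
  ord <- order(windows$chrom, windows$start)
  if (!identical(ord, seq_len(nrow(windows)))) {
    stopf("windows must be in genomic order (chrom, then start)")
  }
  if (!all(reference_cell_ids %in% cell_ids)) {
    stopf("reference cells must be a subset of cell_ids")
  }
  rownames(residuals) <- cell_ids
  structure(list(residuals = residuals, windows = windows,
                 cell_ids = cell_ids,
                 reference_cell_ids = reference_cell_ids),
            class = "CNVProfile")
}

#' Estimate CNV residuals from normalised expression
#'
#' Per gene, expression is centered by the reference-cell mean and clipped
#' to +/- 3 reference SDs (falling back to the overall SD when the
#' reference is constant); genes are then averaged in consecutive blocks of
#' `window_size_genes` along the genome, and each cell's profile is
#' re-centered at its median. This is a deliberately simple moving-average
#' smoother, not an HMM caller.
#'
#' @param norm Normalised expression matrix (cells x genes), cell ids as
#'   row names.
#' @param gene_positions Data frame (gene, chrom, start, end); genes absent
#'   from it are dropped with a warning.
#' @param reference_cells At least 10 cell ids forming the diploid baseline.
#' @param window_size_genes Genes per window (default 10).
#' @return A [cnv_profile()].
#' @export
estimate_cnv_residuals <- function(norm, gene_positions, reference_cells,
                                   window_size_genes = 10) {
  if (length(reference_cells) < 10) stopf("need at least 10 reference cells")
  genes <- colnames(norm)
  placed <- intersect(genes, gene_positions$gene)
  if (length(placed) < length(genes)) {
    warnf("%d gene(s) without genomic position dropped",
          length(genes) - length(placed))
  }
  if (!length(placed)) stopf("no genes with genomic positions")
  pos <- gene_positions[match(placed, gene_positions$gene), , drop = FALSE]
  ord <- order(pos$chrom, pos$start)
  pos <- pos[ord, , drop = FALSE]
  expr <- as.matrix(norm[, pos$gene, drop = FALSE])
  ref <- expr[reference_cells, , drop = FALSE]
  centered <- sweep(expr, 2, colMeans(ref), `-`)
  sds <- apply(ref, 2, stats::sd)
  fallback <- apply(centered, 2, stats::sd)
  sds <- ifelse(sds > 0, sds, fallback)
  lim <- 3 * sds
  clipped <- pmin(pmax(centered, rep(-lim, each = nrow(centered))),
                  rep(lim, each = nrow(centered)))
  # consecutive gene blocks per chromosome
  res_cols <- list(); win_rows <- list()
  for (ch in unique(pos$chrom)) {
    idx <- which(pos$chrom == ch)
    blocks <- split(idx, ceiling(seq_along(idx) / window_size_genes))
    for (b in blocks) {
      res_cols[[length(res_cols) + 1L]] <-
        rowMeans(clipped[, b, drop = FALSE])
      win_rows[[length(win_rows) + 1L]] <-
        data.frame(chrom = ch, start = min(pos$start[b]),
                   end = max(pos$end[b]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(cbind, res_cols)
  res <- res - apply(res, 1, stats::median)
  cnv_profile(res, do.call(rbind, win_rows), rownames(expr), reference_cells)
}

#' Quadratic CNV score per cell
#'
#' `score[c] = sum over windows of residuals[c, w]^2` — a
#' departure-from-diploid energy.
#'
#' @param profile A [cnv_profile()].
#' @return Named numeric vector of per-cell scores.
#' @export
cnv_score <- function(profile) {
  stopifnot(inherits(profile, "CNVProfile"))
  rowSums(profile$residuals^2)
}

#' Classify cells as malignant by CNV score
#'
#' Threshold = mean + 2 x sample SD (n - 1 denominator) of the reference
#' cells' scores; a cell is malignant iff its score strictly exceeds the
#' threshold.
#'
#' @param scores Named per-cell scores from [cnv_score()].
#' @param reference_cell_ids At least 2 reference cell ids.
#' @return Named logical vector.
#' @export
call_malignant <- function(scores, reference_cell_ids) {
  if (length(reference_cell_ids) < 2) stopf("need at least 2 reference cells")
  ref <- scores[reference_cell_ids]
  s <- stats::sd(ref)
  if (s == 0) {
    warnf("reference scores have zero variance; threshold equals their mean")
    s <- 0
  }
  threshold <- mean(ref) + 2 * s
  scores > threshold
}

# Assign each window to the chromosome arm containing the majority of its
# span. Returns a data.frame (chrom, arm) aligned to the windows; windows
# outside every arm get NA.
assign_windows_to_arms <- function(windows, cytoband) {
  ext <- do.call(rbind, by(as.data.frame(cytoband),
                           list(cytoband$chrom, cytoband$arm),
                           function(d) data.frame(chrom = d$chrom[1],
                                                  arm = d$arm[1],
                                                  a_start = min(d$start),
                                                  a_end = max(d$end),
                                                  stringsAsFactors = FALSE)))
  out <- data.frame(chrom = windows$chrom, arm = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(windows))) {
    cand <- ext[ext$chrom == windows$chrom[i], , drop = FALSE]
    if (!nrow(cand)) next
    ov <- pmin(windows$end[i], cand$a_end) - pmax(windows$start[i], cand$a_start)
    ov[ov < 0] <- 0
    if (max(ov) > 0) out$arm[i] <- cand$arm[which.max(ov)]
  }
  out
}

# canonical event string, e.g. chr5 q gain -> "5q+"
event_string <- function(chrom, arm, direction) {
  if (!length(chrom)) return(character(0))
  paste0(sub("^chr", "", chrom), arm, ifelse(direction == "gain", "+", "-"))
}

#' Map per-cell CNV profiles to arm-level gain/loss events
#'
#' Each window is assigned to the p or q arm containing the majority of its
#' span; per cell and arm, the mean residual over the arm's windows labels
#' the arm gained (mean > `gain_cut`) or lost (mean < `loss_cut`). Events
#' are encoded as strings like `"5q+"` or `"7p-"`.
#'
#' @param profile A [cnv_profile()].
#' @param cytoband A [cytoband_table()] covering the profile's chromosomes.
#' @param gain_cut,loss_cut Mean-residual thresholds (defaults +0.3/-0.3).
#' @return Named list (by cell id) of sorted event-string vectors.
#' @export
map_events_to_arms <- function(profile, cytoband, gain_cut = 0.3,
                               loss_cut = -0.3) {
  stopifnot(inherits(profile, "CNVProfile"))
  arm_of <- assign_windows_to_arms(profile$windows, cytoband)
  key <- paste(arm_of$chrom, arm_of$arm)
  keep <- !is.na(arm_of$arm)
  res <- profile$residuals
  arm_keys <- unique(key[keep])
  # per-arm mean residual matrix: cells x arms
  arm_means <- vapply(arm_keys, function(k) {
    rowMeans(res[, key == k & keep, drop = FALSE])
  }, numeric(nrow(res)))
  if (is.null(dim(arm_means))) arm_means <- matrix(arm_means, nrow = nrow(res))
  parts <- strsplit(arm_keys, " ", fixed = TRUE)
  chroms <- vapply(parts, `[[`, character(1), 1L)
  arms <- vapply(parts, `[[`, character(1), 2L)
  events <- lapply(seq_len(nrow(res)), function(i) {
    gained <- arm_means[i, ] > gain_cut
    lost <- arm_means[i, ] < loss_cut
    ev <- c(event_string(chroms[gained], arms[gained], "gain"),
            event_string(chroms[lost], arms[lost], "loss"))
    sort(ev)
  })
  names(events) <- profile$cell_ids
  events
}

#' Collapse cells with identical arm-level event sets into subclones
#'
#' @param event_sets Named list of per-cell event-string vectors, as from
#'   [map_events_to_arms()].
#' @return Data frame (class `SubcloneTable`): key ('|'-joined sorted
#'   events, "" for diploid), a list-column `events`, n_cells, fraction
#'   (fractions sum to 1).
#' @export
collapse_subclones <- function(event_sets) {
  if (!length(event_sets)) stopf("no cells given")
  keys <- vapply(event_sets, function(e) paste(sort(e), collapse = "|"),
                 character(1))
  tab <- table(keys)
  res <- data.frame(key = names(tab), n_cells = as.integer(tab),
                    fraction = as.integer(tab) / length(keys),
                    stringsAsFactors = FALSE)
  res$events <- lapply(res$key, function(k) {
    if (!nzchar(k)) character(0) else strsplit(k, "|", fixed = TRUE)[[1]]
  })
  res <- res[order(-res$n_cells, res$key), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("SubcloneTable", "data.frame")
  res
}

#' Build a clonal tree from subclones by event-set inclusion
#'
#' The root is the empty event set (added with fraction 0 if no diploid
#' subclone exists). Each subclone's parent is the subclone whose event set
#' is the largest proper subset of its own; ties are broken by larger cell
#' fraction, then by lexicographically smallest event-set key. Subclones
#' with no proper subset among the others attach to the root. Every edge
#' therefore satisfies parent events being a strict subset of child events.
#'
#' @param subclones A [collapse_subclones()] table.
#' @return List of class `ClonalTree` with a `nodes` data frame (key,
#'   n_cells, fraction, parent_key).
#' @export
build_clonal_tree <- function(subclones) {
  nodes <- as.data.frame(subclones, stringsAsFactors = FALSE)
  if (!any(nodes$key == "")) {
    root <- data.frame(key = "", n_cells = 0L, fraction = 0,
                       stringsAsFactors = FALSE)
    root$events <- list(character(0))
    nodes <- rbind(nodes[, c("key", "n_cells", "fraction", "events")],
                   root[, c("key", "n_cells", "fraction", "events")])
  }
  nodes$parent_key <- NA_character_
  for (i in seq_len(nrow(nodes))) {
    if (nodes$key[i] == "") next
    ev <- nodes$events[[i]]
    is_proper_subset <- vapply(seq_len(nrow(nodes)), function(j) {
      j != i && length(nodes$events[[j]]) < length(ev) &&
        all(nodes$events[[j]] %in% ev)
    }, logical(1))
    cand <- which(is_proper_subset)
    cand <- cand[nodes$key[cand] != ""]
    if (!length(cand)) {
      nodes$parent_key[i] <- ""
      next
    }
    sizes <- vapply(cand, function(j) length(nodes$events[[j]]), integer(1))
    cand <- cand[sizes == max(sizes)]
    if (length(cand) > 1) {
      fr <- nodes$fraction[cand]
      cand <- cand[fr == max(fr)]
    }
    if (length(cand) > 1) cand <- cand[order(nodes$key[cand])][1]
    nodes$parent_key[i] <- nodes$key[cand]
  }
  structure(list(nodes = nodes), class = "ClonalTree")
}

#' Serialise a clonal tree to Newick
#'
#' Node labels are the '|'-joined event strings (root labelled "root");
#' branch lengths are cell fractions (root gets length 0); fractions are
#' rounded to 4 decimals.
#'
#' @param tree A [build_clonal_tree()] result.
#' @return Newick string terminated by ";".
#' @export
serialize_newick <- function(tree) {
  stopifnot(inherits(tree, "ClonalTree"))
  nodes <- tree$nodes
  fmt <- function(x) format(round(x, 4), trim = TRUE, scientific = FALSE)
  recurse <- function(key) {
    i <- which(nodes$key == key)
    children <- which(!is.na(nodes$parent_key) & nodes$parent_key == key)
    children <- children[order(nodes$key[children])]
    label <- if (key == "") "root" else key
    len <- if (key == "") 0 else nodes$fraction[i]
    inner <- if (length(children)) {
      paste0("(", paste(vapply(children, function(j) recurse(nodes$key[j]),
                               character(1)), collapse = ","), ")")
    } else ""
    paste0(inner, label, ":", fmt(len))
  }
  paste0(recurse(""), ";")
}
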