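test_that("AUC and exact p behave on separated, identical and tied groups", {
  norm <- matrix(c(4, 5, 6, 1, 2, 3), ncol = 1,
                 dimnames = list(sprintf("c%d", 1:6), "g"))
  res <- wilcoxon_auc(norm, 1:3, 4:6)
  expect_equal(res$auc, 1)
  expect_equal(res$p, 0.1)   # 2 / choose(6, 3) by enumeration

  norm2 <- matrix(rep(c(1, 2, 3), 2), ncol = 1,
                  dimnames = list(sprintf("c%d", 1:6), "g"))
  expect_equal(wilcoxon_auc(norm2, 1:3, 4:6)$auc, 0.5)

  tied <- matrix(rep(2, 6), ncol = 1,
                 dimnames = list(sprintf("c%d", 1:6), "g"))
  res3 <- wilcoxon_auc(tied, 1:3, 4:6)
  expect_equal(res3$auc, 0.5)
  expect_equal(res3$p, 1)
})

test_that("AUC equals brute-force pair counting and is anti-symmetric", {
  withr::local_seed(101)
  for (rep in 1:20) {
    n_in <- sample(2:10, 1); n_out <- sample(2:10, 1)
    vals <- sample(0:4, n_in + n_out, replace = TRUE)  # heavy ties
    norm <- matrix(vals, ncol = 1,
                   dimnames = list(sprintf("c%d", seq_along(vals)), "g"))
    a <- wilcoxon_auc(norm, seq_len(n_in), n_in + seq_len(n_out))
    b <- wilcoxon_auc(norm, n_in + seq_len(n_out), seq_len(n_in))
    expect_equal(a$auc, brute_auc(vals[seq_len(n_in)], vals[n_in + seq_len(n_out)]))
    expect_equal(a$auc + b$auc, 1)
  }
})

test_that("large-sample p matches the tie-corrected normal approximation", {
  withr::local_seed(7)
  x <- rnorm(40); y <- rnorm(35) + 0.5
  norm <- matrix(c(x, y), ncol = 1,
                 dimnames = list(sprintf("c%d", 1:75), "g"))
  ours <- wilcoxon_auc(norm, 1:40, 41:75)$p
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("log2FC uses back-transformed means with pseudocount", {
  norm <- matrix(c(log(3), log(3), 0, 0), ncol = 1,
                 dimnames = list(sprintf("c%d", 1:4), "g"))
  res <- wilcoxon_auc(norm, 1:2, 3:4)
  expect_equal(res$log2fc, log2((2 + 1) / (0 + 1)))  # mean(expm1) = 2 vs 0
})

test_that("marker retention applies the pct/p_adj/log2fc criteria", {
  # Bonferroni: p = 0.001 with 100 genes tested -> p_adj = 0.1 -> excluded
  expect_equal(min(1, 0.001 * 100), 0.1)
  cfg <- simulation_config(cells_per_sample = 200, samples_per_group = 1,
                           seed = 21)
  sim <- generate_dataset(cfg)
  d <- normalize_log1p(sim$dataset)
  mk <- find_all_markers(as.matrix(d$norm), d$meta$cluster)
  expect_true(all(mk$pct_in >= 0.25))
  expect_true(all(mk$p_adj < 0.05))
  expect_true(all(mk$log2fc > 0.25))
  expect_true(all(mk$p_adj >= mk$p))
  # every planted marker of every cluster is recovered at shift 2
  for (cl in cfg$clusters) {
    expect_true(all(cl$marker_genes %in% mk$gene[mk$cluster == cl$name]))
  }
  # a huge-effect gene detected in under 25% of the cluster is excluded
  n <- 40
  vals <- c(rep(8, 4), rep(0, 16), rep(0, n - 20))  # pct_in = 0.2
  norm <- cbind(rare = vals, filler = rep(c(1, 2), n / 2))
  rownames(norm) <- sprintf("c%d", 1:n)
  mk2 <- find_all_markers(norm, rep(c("A", "B"), each = n / 2))
  expect_false("rare" %in% mk2$gene[mk2$cluster == "A"])
})

test_that("annotation assigns reference types and flags ambiguity", {
  genes <- c("EPCAM", "KRT8", "CAPS", "CD3D", "CD3E")
  norm <- rbind(matrix(c(3, 3, 3, 0, 0), nrow = 5, ncol = 5, byrow = TRUE),
                matrix(c(0, 0, 0, 3, 3), nrow = 5, ncol = 5, byrow = TRUE))
  colnames(norm) <- genes
  rownames(norm) <- sprintf("c%d", 1:10)
  clusters <- rep(c("k_epi", "k_t"), each = 5)
  ann <- suppressWarnings(annotate_clusters(norm, clusters))
  expect_equal(ann$cell_type[ann$cluster == "k_epi"], "Epithelial")
  expect_equal(ann$cell_type[ann$cluster == "k_t"], "T/NK")
  expect_false(any(ann$ambiguous))

  # exactly equal scores tie -> ambiguous
  norm_tie <- norm
  norm_tie[1:5, ] <- 1
  ann_tie <- suppressWarnings(annotate_clusters(norm_tie, clusters))
  expect_true(ann_tie$ambiguous[ann_tie$cluster == "k_epi"])

  expect_error(
    suppressWarnings(annotate_clusters(matrix(1, 2, 1,
                                              dimnames = list(NULL, "XXX")),
                                       c("a", "b"))),
    "no reference marker genes")
})

test_that("composition percentages reproduce the published lineage table", {
  counts <- c(`T/NK` = 99152, Plasma = 5963, B = 18350, Myeloid = 118556,
              CAF = 3908, Epithelial = 68911, Mast = 6272,
              Endothelial = 6499)
  tab <- composition_table(counts)
  expect_equal(sum(tab$n), 327611)
  get <- function(t) tab$pct[tab$cell_type == t]
  expect_equal(get("T/NK"), 30.27)
  expect_equal(get("Myeloid"), 36.19)
  expect_equal(get("Epithelial"), 21.03)
  expect_equal(get("Plasma"), 1.82)
  expect_equal(get("B"), 5.60)
  expect_equal(get("Endothelial"), 1.98)
  expect_lt(abs(sum(tab$pct) - 100), 0.05)

  expect_equal(composition_table(c(only = 12))$pct, 100.00)

  meta <- data.frame(cell_id = sprintf("c%d", 1:6), sample_id = "s1",
                     group = rep(c("MPLC_Tumour", "SPLC_Tumour"), each = 3),
                     cluster = "k",
                     cell_type = c("A", "A", "B", "B", "B", "B"))
  bygroup <- composition_table(meta, by = "group")
  expect_equal(bygroup$pct[bygroup$stratum == "MPLC_Tumour" &
                           bygroup$cell_type == "A"], 66.67)
})

test_that("top-N signatures sort by log2FC with p then gene tie-breaks", {
  mk <- data.frame(gene = sprintf("g%02d", 1:12), cluster = "k",
                   log2fc = seq(1.2, 0.1, by = -0.1), p = 0.01)
  expect_equal(top_n_signature(mk, 10), sprintf("g%02d", 1:10))
  expect_equal(top_n_signature(mk, 0), character(0))
  # tie at the boundary: smaller p wins
  mk2 <- data.frame(gene = c("gA", "gB", "gC"), cluster = "k",
                    log2fc = c(2, 1, 1), p = c(0.01, 0.005, 0.001))
  expect_equal(top_n_signature(mk2, 2), c("gA", "gC"))
  expect_warning(res <- top_n_signature(mk2, 5), "only 3")
  expect_length(res, 3)
})

test_that("quadrant classification tallies positivity by raw counts", {
  counts <- cbind(CXCL9 = c(0, 0, 1, 2, 0, 3, 0, 1, 0, 4),
                  SPP1  = c(3, 0, 0, 1, 0, 0, 2, 5, 0, 0))
  ds <- make_tiny_dataset(counts, genes = c("CXCL9", "SPP1"),
                          clusters = rep("mac", 10))
  res <- classify_quadrants(ds)
  expect_equal(res$cells$label[1], "CXCL9-SPP1+")
  expect_equal(res$cells$label[2], "CXCL9-SPP1-")
  fr <- res$fractions
  expect_equal(sum(fr$fraction), 1)
  expect_equal(fr$fraction[fr$label == "CXCL9-SPP1-"], 3 / 10)
  expect_equal(fr$fraction[fr$label == "CXCL9-SPP1+"], 2 / 10)
  expect_equal(fr$fraction[fr$label == "CXCL9+SPP1-"], 3 / 10)
  expect_equal(fr$fraction[fr$label == "CXCL9+SPP1+"], 2 / 10)

  zero <- make_tiny_dataset(matrix(0L, 3, 2), genes = c("CXCL9", "SPP1"))
  expect_true(all(classify_quadrants(zero)$cells$label == "CXCL9-SPP1-"))
  expect_error(classify_quadrants(zero, gene_x = "NOPE"), "absent")
})
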