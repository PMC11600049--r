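toy_profile <- function(res, chroms = "chr1") {
  n_w <- ncol(res)
  windows <- data.frame(chrom = chroms,
                        start = seq(0, by = 1e6, length.out = n_w),
                        end = seq(1e6, by = 1e6, length.out = n_w))
  cells <- sprintf("c%d", seq_len(nrow(res)))
  cnv_profile(res, windows, cells, reference_cell_ids = cells[1])
}

test_that("CNV score is the quadratic sum, homogeneous and window-permutation invariant", {
  prof <- toy_profile(rbind(c(0, 0, 0), c(0.5, -0.5, 1.0), c(1, 1, 1)))
  s <- cnv_score(prof)
  expect_equal(unname(s), c(0, 1.5, 3))
  prof2 <- toy_profile(rbind(c(0, 0, 0), c(1.0, 0.5, -0.5), c(1, 1, 1)))
  expect_equal(cnv_score(prof2), s)            # permutation invariance
  prof4 <- toy_profile(2 * prof$residuals)
  expect_equal(unname(cnv_score(prof4))[2], 4 * 1.5)  # homogeneity degree 2
})

test_that("malignancy threshold is reference mean + 2 sample SDs, strict", {
  # reference scores with mean 2, sd 0.5 -> threshold 3
  scores <- c(r1 = 1.5, r2 = 2.0, r3 = 2.5, t1 = 3.5, t2 = 2.9)
  ref_sd <- sd(c(1.5, 2, 2.5))
  calls <- call_malignant(scores, c("r1", "r2", "r3"))
  thr <- 2 + 2 * ref_sd
  expect_equal(calls, scores > thr)
  expect_true(calls[["t1"]]); expect_false(calls[["t2"]])

  same <- c(a = 1, b = 1, c = 1)
  expect_warning(calls2 <- call_malignant(same, c("a", "b")), "zero variance")
  expect_false(any(calls2))   # score equals mean, not strictly above
})

test_that("windows map to arms by majority overlap and cutoffs label events", {
  cb <- toy_cytoband(chroms = "chr5", p_len = 50e6, q_len = 70e6)
  # window straddling the centromere 60%/40% on the p side
  win <- data.frame(chrom = "chr5",
                    start = c(0, 20e6, 44e6, 60e6),
                    end = c(20e6, 44e6, 54e6, 120e6))
  arm <- sctme:::assign_windows_to_arms(win, cb)
  expect_equal(arm$arm, c("p", "p", "p", "q"))

  res <- rbind(c(0, 0, 0, 0.5),    # q gain
               c(0, 0, 0, 0))      # neutral
  prof <- cnv_profile(res, win, c("c1", "c2"), "c2")
  ev <- map_events_to_arms(prof, cb)
  expect_equal(ev$c1, "5q+")
  expect_equal(ev$c2, character(0))
})

test_that("subclone collapsing groups identical event sets with exact fractions", {
  sets <- list(c1 = c("A", "B"), c2 = c("B", "A"), c3 = "A")
  sub <- collapse_subclones(sets)
  expect_equal(nrow(sub), 2)
  expect_equal(sub$fraction[sub$key == "A|B"], 2 / 3)
  expect_equal(sub$fraction[sub$key == "A"], 1 / 3)
  expect_equal(sum(sub$fraction), 1)

  one <- collapse_subclones(list(a = "X", b = "X"))
  expect_equal(one$fraction, 1)
  dip <- collapse_subclones(list(a = character(0), b = character(0)))
  expect_equal(dip$key, "")
})

test_that("clonal trees follow strict event-set inclusion with stated tie-breaks", {
  mk_sub <- function(keys, fractions) {
    df <- data.frame(key = keys, n_cells = round(fractions * 100),
                     fraction = fractions, stringsAsFactors = FALSE)
    df$events <- lapply(keys, function(k)
      if (nzchar(k)) strsplit(k, "|", fixed = TRUE)[[1]] else character(0))
    class(df) <- c("SubcloneTable", "data.frame")
    df
  }
  chain <- build_clonal_tree(mk_sub(c("", "5q+", "5q+|7p-"),
                                    c(0, 1 / 3, 2 / 3)))
  nd <- chain$nodes
  expect_equal(nd$parent_key[nd$key == "5q+"], "")
  expect_equal(nd$parent_key[nd$key == "5q+|7p-"], "5q+")

  forked <- build_clonal_tree(mk_sub(c("A", "B"), c(0.5, 0.5)))
  expect_true(all(forked$nodes$parent_key[forked$nodes$key != ""] == ""))

  # tie on subset size broken by larger fraction
  tied <- build_clonal_tree(mk_sub(c("A", "A|B", "A|C", "A|B|C"),
                                   c(0.1, 0.4, 0.3, 0.2)))
  expect_equal(tied$nodes$parent_key[tied$nodes$key == "A|B|C"], "A|B")

  # every edge satisfies the strict-superset invariant
  for (tree in list(chain, forked, tied)) {
    nd <- tree$nodes
    for (i in seq_len(nrow(nd))) {
      pk <- nd$parent_key[i]
      if (is.na(pk)) next
      parent_ev <- nd$events[[which(nd$key == pk)]]
      expect_true(all(parent_ev %in% nd$events[[i]]))
      expect_lt(length(parent_ev), length(nd$events[[i]]))
    }
  }

  nwk <- serialize_newick(chain)
  expect_equal(nwk, "((5q+|7p-:0.6667)5q+:0.3333)root:0;")
  root_only <- build_clonal_tree(mk_sub("", 1))
  expect_equal(serialize_newick(root_only), "root:0;")
})

test_that("Newick output round-trips through ape", {
  skip_if_not_installed("ape")
  sets <- list(a = "5q+", b = "5q+", c = c("5q+", "7p-"), d = "1p-")
  tree <- build_clonal_tree(collapse_subclones(sets))
  ph <- ape::read.tree(text = serialize_newick(tree))
  expect_s3_class(ph, "phylo")
  labels <- c(ph$tip.label, ph$node.label)
  expect_true(all(c("root", "5q+", "1p-") %in% labels))
  expect_equal(sort(ph$edge.length), sort(c(0.5, 0.25, 0.25)))
})

test_that("residual estimation centers on the reference and finds planted arms", {
  withr::local_seed(17)
  n_ref <- 100; n_tum <- 30; n_genes <- 60
  pos <- data.frame(gene = sprintf("g%02d", 1:n_genes),
                    chrom = rep(c("chr1", "chr2"), each = 30),
                    start = rep(seq(0, by = 2e6, length.out = 30), 2),
                    end = rep(seq(2e6, by = 2e6, length.out = 30), 2))
  base <- matrix(rnorm((n_ref + n_tum) * n_genes, 1, 0.2),
                 nrow = n_ref + n_tum)
  # plant a gain on the first chr2 window (genes 31..40) in tumour cells;
  # the +1 shift is clipped to 3 reference SDs (~0.6) by design
  base[(n_ref + 1):(n_ref + n_tum), 31:40] <-
    base[(n_ref + 1):(n_ref + n_tum), 31:40] + 1
  rownames(base) <- c(sprintf("ref%03d", 1:n_ref), sprintf("tum%03d", 1:n_tum))
  colnames(base) <- pos$gene
  prof <- estimate_cnv_residuals(base, pos, sprintf("ref%03d", 1:n_ref),
                                 window_size_genes = 10)
  expect_equal(nrow(prof$windows), 6)
  ref_rows <- startsWith(rownames(prof$residuals), "ref")
  expect_true(all(abs(colMeans(prof$residuals[ref_rows, ])) < 0.05))
  gained_win <- which(prof$windows$chrom == "chr2")[1]
  tum_mean <- mean(prof$residuals[!ref_rows, gained_win])
  expect_gt(tum_mean, 0.3)
  other <- setdiff(seq_len(nrow(prof$windows)), gained_win)
  expect_true(all(abs(colMeans(prof$residuals[!ref_rows, other])) < 0.2))

  # window size 1: residual equals centered clipped expression re-centered
  # at the cell median
  prof1 <- estimate_cnv_residuals(base, pos, sprintf("ref%03d", 1:n_ref),
                                  window_size_genes = 1)
  ref <- base[sprintf("ref%03d", 1:n_ref), ]
  centered <- sweep(base, 2, colMeans(ref), `-`)
  lim <- 3 * apply(ref, 2, sd)
  clipped <- pmin(pmax(centered, rep(-lim, each = nrow(base))),
                  rep(lim, each = nrow(base)))
  expected <- clipped - apply(clipped, 1, median)
  expect_equal(unname(prof1$residuals), unname(expected), tolerance = 1e-12)

  expect_warning(
    estimate_cnv_residuals(base, pos[-1, ], sprintf("ref%03d", 1:n_ref)),
    "without genomic position")
  expect_error(estimate_cnv_residuals(base, pos, "ref001"), "at least 10")
})
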