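test_that("module score is zero on degenerate universes and matches hand arithmetic", {
  # constant matrix
  const <- matrix(2, 4, 30, dimnames = list(sprintf("c%d", 1:4),
                                            sprintf("g%d", 1:30)))
  expect_true(all(module_score(const, c("g1", "g2"), n_bins = 3) == 0))

  # 2-bin toy: bins homogeneous outside the set gene, so the control mean
  # is closed-form. Low bin: g1..g3 at (0,0,1); high bin: g4 (set) at
  # (3,4,5), g5/g6 at (2,3,4).
  norm <- rbind(c(0, 0, 0, 3, 2, 2),
                c(0, 0, 0, 4, 3, 3),
                c(1, 1, 1, 5, 4, 4))
  dimnames(norm) <- list(sprintf("c%d", 1:3), sprintf("g%d", 1:6))
  sc <- module_score(norm, "g4", n_bins = 2, n_ctrl = 10, seed = 1)
  expect_equal(unname(sc), c(3, 4, 5) - c(2, 3, 4))

  expect_error(module_score(norm, "absent"), "no gene-set genes")
})

test_that("Spearman correlation handles monotone, tied and degenerate input", {
  expect_equal(spearman_corr(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_corr(1:6, rev(1:6))$rho, -1)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(spearman_corr(x, y)$rho,
               cor(x, y, method = "spearman"))
  # exact enumeration at n = 3: P(|rho| >= 1) = 2/6
  expect_equal(spearman_corr(c(1, 2, 3), c(1, 2, 3))$p, 1 / 3)
  # t approximation for n > 8 agrees with cor.test
  withr::local_seed(2)
  a <- rnorm(30); b <- a + rnorm(30)
  ref <- suppressWarnings(cor.test(a, b, method = "spearman"))
  ours <- spearman_corr(a, b)
  expect_equal(ours$rho, unname(ref$estimate))
  expect_equal(ours$p, ref$p.value, tolerance = 0.02)
  expect_error(spearman_corr(c(1, 1, 1), 1:3), "zero variance")
})

test_that("bulk signature scores are mean per-gene z-scores of log2 expression", {
  m <- matrix(c(0, 3), 2, 1, dimnames = list(c("s1", "s2"), "g1"))
  sc <- signature_score_bulk(m, "g1")
  expect_equal(unname(sc), c(-1, 1) / sqrt(2), tolerance = 1e-6)

  # single gene: score equals that gene's z-scores
  withr::local_seed(4)
  m2 <- matrix(rexp(8 * 3), 8, 3,
               dimnames = list(sprintf("s%d", 1:8), c("a", "b", "c")))
  lg <- log2(m2 + 1)
  expect_equal(unname(signature_score_bulk(m2, "b")),
               unname((lg[, "b"] - mean(lg[, "b"])) / sd(lg[, "b"])))

  # multiplying a gene on the linear scale so its log2 shifts by a constant
  # leaves scores unchanged
  m3 <- m2
  m3[, "a"] <- 2^(log2(m2[, "a"] + 1) + 3) - 1
  expect_equal(signature_score_bulk(m3, c("a", "b")),
               signature_score_bulk(m2, c("a", "b")))

  m4 <- cbind(m2, flat = 1)
  expect_warning(sc4 <- signature_score_bulk(m4, c("a", "flat")),
                 "zero variance")
  expect_equal(sc4, signature_score_bulk(m2, "a"))
})

test_that("median split sends ties to the low group", {
  expect_equal(unname(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_true(all(median_split(rep(2, 5)) == "low"))
  expect_equal(unname(median_split(c(1, 2, 3))), c("low", "low", "high"))
})

test_that("KM curves follow the product-limit bookkeeping", {
  none <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(none$surv == 1))
  both <- km_curve(c(1, 2), c(1, 1))
  expect_equal(both$surv, c(0.5, 0))
  cens <- km_curve(c(1, 2), c(1, 0))
  expect_equal(cens$surv, c(0.5, 0.5))
  # no censoring: KM equals the empirical survival function
  withr::local_seed(11)
  t <- rexp(40)
  km <- km_curve(t, rep(1, 40))
  ecdf_surv <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$surv, ecdf_surv)
})

test_that("log-rank statistic matches hand-tabulated O/E/V and is label-symmetric", {
  # 6-subject worked example with one censored record
  times <- c(1, 3, 5, 2, 4, 6)
  events <- c(1, 1, 1, 1, 1, 0)
  groups <- rep(c("A", "B"), each = 3)
  res <- logrank_test(groups, times, events)
  expect_equal(res$statistic, logrank_oracle(groups, times, events),
               tolerance = 1e-12)
  expect_equal(res$p, pchisq(res$statistic, 1, lower.tail = FALSE))
  flipped <- logrank_test(rev(groups), times, events)
  expect_equal(flipped$statistic, res$statistic)

  # two identical copies of the same data as the two groups -> statistic 0
  same <- logrank_test(rep(c("A", "B"), each = 4),
                       rep(c(1, 2, 3, 4), 2), rep(1, 8))
  expect_lt(same$statistic, 1e-12)
  expect_error(logrank_test(rep("A", 4), 1:4, rep(1, 4)), "two groups")
})

test_that("Cox estimates maximise the Breslow partial likelihood", {
  # exchangeable groups: duplicated data under both labels -> HR 1
  t <- c(1, 2, 3, 4); e <- c(1, 1, 1, 0)
  fit <- cox_univariate(rep(0:1, each = 4), c(t, t), c(e, e))
  expect_equal(fit$hr, 1, tolerance = 1e-6)
  expect_equal(fit$hr, exp(fit$log_hr))
  expect_lte(fit$ci_low, fit$hr); expect_gte(fit$ci_high, fit$hr)

  # grid-search oracle on small toys (with ties to exercise Breslow)
  withr::local_seed(19)
  n_checked <- 0
  while (n_checked < 6) {
    n <- sample(6:10, 1)
    x <- rbinom(n, 1, 0.5)
    times <- sample(1:5, n, replace = TRUE)
    events <- rbinom(n, 1, 0.8)
    if (sum(events) < 3 || sd(x) == 0) next
    fit <- tryCatch(cox_univariate(x, times, events), error = function(e) NULL)
    if (is.null(fit) || abs(fit$log_hr) > 2.5) next
    expect_equal(fit$log_hr, grid_cox(x, times, events), tolerance = 1e-4)
    n_checked <- n_checked + 1
  }

  expect_error(cox_univariate(rep(1, 6), 1:6, rep(1, 6)), "constant")
  # complete separation is reported, not silently returned
  expect_error(cox_univariate(c(0, 0, 0, 1, 1, 1), c(1, 2, 3, 10, 11, 12),
                              rep(1, 6)), "Cox fit failed|monotone")
})

test_that("group comparison reuses the rank-sum engine with star mapping", {
  expect_equal(wilcoxon_group_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  sep <- wilcoxon_group_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sep$p, 0.1)
  expect_equal(sep$stars, "ns")
  withr::local_seed(3)
  big <- wilcoxon_group_test(rnorm(40) + 3, rnorm(40))
  expect_lt(big$p, 0.001)
  expect_equal(big$stars, "***")
})

test_that("the signature pipeline recovers a planted hazard ratio", {
  coh <- generate_survival_cohort(
    survival_simulation_config(n_patients = 600, true_hr = 2, seed = 31))
  sa <- survival_signature_analysis(coh$table, sprintf("SIG%02d", 1:10))
  # high-score group is essentially the latent high-risk group
  agree <- mean((sa$groups == "high") == (coh$truth$risk_group == 1))
  expect_gt(agree, 0.95)
  expect_gt(sa$cox$hr, 1.5)
  expect_lt(sa$logrank$p, 0.01)
  expect_named(sa$km, c("high", "low"))
})
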