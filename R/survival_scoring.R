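# Module scores, Spearman co-expression, group comparisons, and the
# signature survival pipeline: per-sample z-scored signature means, median
# split into high/low groups, Kaplan-Meier curves, log-rank test and a
# univariate Cox model (Breslow ties).

#' Control-matched module score per cell
#'
#' Genes are binned into `n_bins` by average expression; for each gene-set
#' gene, `n_ctrl` control genes are sampled from the non-set genes of its
#' bin (with replacement when the bin is small; set genes are used as a
#' fallback pool only when a bin holds nothing else); the score is the mean
#' expression of the set genes minus the mean expression of the control
#' pool, per cell.
#'
#' @param norm Normalised expression matrix (cells x genes).
#' @param gene_set Character vector; at least one gene must be present.
#' @param n_bins,n_ctrl Binning and control-pool parameters (defaults 24
#'   and 100).
#' @param seed Integer seed (control sampling is the only randomness).
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(norm, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1) {
  genes <- colnames(norm)
  present <- intersect(gene_set, genes)
  if (!length(present)) stopf("no gene-set genes present in the matrix")
  avg <- Matrix::colMeans(norm)
  n_bins <- min(n_bins, length(genes))
  bins <- cut(rank(avg, ties.method = "average"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- genes
  with_seed(seed, {
    ctrl <- unlist(lapply(present, function(g) {
      pool <- setdiff(genes[bins == bins[[g]]], present)
      if (!length(pool)) pool <- genes[bins == bins[[g]]]
      sample(pool, n_ctrl, replace = length(pool) < n_ctrl)
    }))
  })
  set_mean <- Matrix::rowMeans(norm[, present, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(norm[, ctrl, drop = FALSE])
  score <- as.numeric(set_mean - ctrl_mean)
  names(score) <- rownames(norm)
  score
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks; exact permutation p value for
#' n <= 8, t approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List (rho, p).
#' @export
spearman_corr <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stopf("need equal-length vectors of size >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("zero variance; Spearman correlation undefined")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    t_stat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(t_stat), df = n - 2))
  }
  list(rho = rho, p = p)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Per-sample signature score from bulk expression
#'
#' Per gene: log2(x + 1) transform, then z-score across samples (sample
#' SD); the score is the mean of the z-scored values over the signature
#' genes. Genes with zero variance are dropped with a warning.
#'
#' @param bulk_expr Numeric matrix, samples x genes.
#' @param signature_genes Character vector; at least one must be present.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_score_bulk <- function(bulk_expr, signature_genes) {
  bulk_expr <- as.matrix(bulk_expr)
  present <- intersect(signature_genes, colnames(bulk_expr))
  if (!length(present)) stopf("no signature genes present in the matrix")
  lg <- log2(bulk_expr[, present, drop = FALSE] + 1)
  sds <- apply(lg, 2, stats::sd)
  if (any(sds == 0)) {
    warnf("signature gene(s) with zero variance dropped: %s",
          paste(present[sds == 0], collapse = ", "))
    lg <- lg[, sds > 0, drop = FALSE]
    if (!ncol(lg)) stopf("all signature genes have zero variance")
  }
  z <- scale(lg)
  score <- rowMeans(z)
  names(score) <- rownames(bulk_expr)
  score
}

#' Median split into high and low groups
#'
#' High iff score > median; scores equal to the median go to low.
#'
#' @param scores Numeric vector (>= 2 samples).
#' @return Character vector ("high"/"low") with the input's names.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stopf("need at least 2 samples")
  m <- stats::median(scores)
  out <- ifelse(scores > m, "high", "low")
  names(out) <- names(scores)
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator; censored times reduce the risk set without
#' producing steps.
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @return Data frame: time, n_risk, n_event, n_censor, surv.
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Observed minus expected events over event times with hypergeometric
#' variance; p from chi-square with 1 degree of freedom.
#'
#' @param group_labels Two-level group label per subject.
#' @param times,events Follow-up times and 0/1 event indicators.
#' @return List (statistic, p).
#' @export
logrank_test <- function(group_labels, times, events) {
  if (length(unique(group_labels)) != 2) stopf("need exactly two groups")
  if (sum(events) < 1) stopf("need at least one event")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ group_labels)
  stat <- sd_$chisq
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards model
#'
#' Breslow tie handling; Newton-Raphson on the partial likelihood to a
#' 1e-9 tolerance; CI = exp(beta +/- 1.96 SE); Wald p.
#'
#' @param covariate Numeric (or two-level) covariate per subject,
#'   non-constant.
#' @param times,events Follow-up times and 0/1 event indicators (>= 2
#'   events).
#' @return List of class `CoxResult`: log_hr, hr, se, ci_low, ci_high, p.
#' @export
cox_univariate <- function(covariate, times, events) {
  if (sum(events) < 2) stopf("need at least 2 events")
  if (is.character(covariate) || is.factor(covariate)) {
    covariate <- as.numeric(factor(covariate)) - 1
  }
  if (stats::sd(covariate) == 0) stopf("covariate is constant")
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ covariate,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        stopf("Cox fit failed: %s", conditionMessage(w))
      }
      suppressWarnings(
        survival::coxph(survival::Surv(times, events) ~ covariate,
                        ties = "breslow",
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 100)))
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(beta) || abs(beta) > 15) {
    stopf("monotone partial likelihood (complete separation); beta = %.2f",
          beta)
  }
  structure(list(log_hr = beta, hr = exp(beta), se = se,
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 p = 2 * stats::pnorm(-abs(beta / se))),
            class = "CoxResult")
}

#' Wilcoxon rank-sum comparison of two sample groups
#'
#' Same engine as the marker module's test, applied to raw value vectors,
#' with the conventional significance stars (* p < .05, ** p < .01,
#' *** p < .001).
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return List (statistic = U of the first group, p, stars).
#' @export
wilcoxon_group_test <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) stopf("empty group")
  pooled <- c(values_a, values_b)
  r <- rank(pooled)
  n_a <- length(values_a)
  U <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  p <- rank_sum_p(r, n_a, U)
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(statistic = U, p = p, stars = stars)
}

#' Signature-based survival stratification
#'
#' Runs the full §-style pipeline: per-sample signature score
#' ([signature_score_bulk()]), median split, Kaplan-Meier curves per
#' group, log-rank test, and a univariate Cox model of high vs low
#' (optionally the continuous score).
#'
#' @param surv_table Data frame with `time`, `event` and one column per
#'   signature gene (linear expression scale).
#' @param signature_genes Character vector of signature genes.
#' @param covariate `"split"` (default) to model high vs low, or
#'   `"score"` for the continuous signature score.
#' @return List: scores, groups, km (per-group curves), logrank, cox.
#' @export
survival_signature_analysis <- function(surv_table, signature_genes,
                                        covariate = c("split", "score")) {
  covariate <- match.arg(covariate)
  expr <- as.matrix(surv_table[, intersect(signature_genes,
                                           names(surv_table)), drop = FALSE])
  rownames(expr) <- surv_table$patient_id %||% rownames(surv_table)
  scores <- signature_score_bulk(expr, signature_genes)
  groups <- median_split(scores)
  km <- lapply(split(seq_along(groups), groups), function(idx) {
    km_curve(surv_table$time[idx], surv_table$event[idx])
  })
  lr <- logrank_test(groups, surv_table$time, surv_table$event)
  cov <- if (covariate == "split") as.numeric(groups == "high") else scores
  cox <- cox_univariate(cov, surv_table$time, surv_table$event)
  list(scores = scores, groups = groups, km = km, logrank = lr, cox = cox)
}
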