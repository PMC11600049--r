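# Independent oracles used across the suite: brute-force implementations
# kept deliberately separate from the package's code paths.

# AUC by exhaustive pair counting, ties counted half
brute_auc <- function(x_in, x_out) {
  s <- 0
  for (a in x_in) for (b in x_out) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(x_in) * length(x_out))
}

# Two-sided Fisher p by explicit hypergeometric enumeration with choose()
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(logp)
  p_obs <- exp(lchoose(m, a) + lchoose(n, k - a) - lchoose(m + n, k))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# GSEA enrichment score by an explicit position-by-position walk
es_oracle <- function(genes, metric, set, p = 1) {
  N <- length(genes)
  hit <- genes %in% set
  nh <- sum(hit)
  w <- abs(metric)^p
  sw <- sum(w[hit])
  cur <- 0
  run <- numeric(N)
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) {
      if (sw > 0) w[i] / sw else 1 / nh
    } else {
      -1 / (N - nh)
    }
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# Breslow partial log-likelihood for a single covariate
breslow_loglik <- function(beta, x, times, events) {
  s <- 0
  for (t in unique(times[events == 1])) {
    d_idx <- which(events == 1 & times == t)
    risk <- which(times >= t)
    s <- s + sum(x[d_idx] * beta) -
      length(d_idx) * log(sum(exp(x[risk] * beta)))
  }
  s
}

# Two-stage grid maximiser of the Breslow partial likelihood (1e-5 grid)
grid_cox <- function(x, times, events) {
  g1 <- seq(-4, 4, by = 0.01)
  ll1 <- vapply(g1, breslow_loglik, numeric(1), x = x, times = times,
                events = events)
  b0 <- g1[which.max(ll1)]
  g2 <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  ll2 <- vapply(g2, breslow_loglik, numeric(1), x = x, times = times,
                events = events)
  g2[which.max(ll2)]
}

# Log-rank chi-square by direct O/E/V tabulation over event times
logrank_oracle <- function(groups, times, events) {
  g <- sort(unique(groups))
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == g[1])
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & groups == g[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Small hand-buildable dataset: counts given explicitly, 4 groups present
make_tiny_dataset <- function(counts, genes = NULL, clusters = NULL,
                              groups = NULL) {
  n <- nrow(counts)
  genes <- genes %||% sprintf("g%d", seq_len(ncol(counts)))
  cells <- sprintf("c%d", seq_len(n))
  meta <- data.frame(
    cell_id = cells,
    sample_id = "s1",
    group = groups %||% rep(tme_groups(), length.out = n),
    cluster = clusters %||% rep("k1", n),
    stringsAsFactors = FALSE)
  expression_dataset(counts, gene_ids = genes, cell_ids = cells, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
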