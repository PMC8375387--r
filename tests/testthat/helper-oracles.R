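# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately written as explicit loops / enumerations with no
# code shared with the package implementation.

# Plain two-group dataset with N(mean, sd) noise, no planted structure.
random_dataset <- function(n_genes = 50L, n1 = 3L, n2 = 3L, seed = 1L,
                           mean_range = c(4, 10), sd = 0.5) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  samples <- c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2)))
  vals <- matrix(runif(n_genes, mean_range[1], mean_range[2]) +
                   rnorm(n_genes * (n1 + n2), 0, sd),
                 nrow = n_genes, dimnames = list(genes, samples))
  g <- c(rep("control", n1), rep("condition", n2))
  names(g) <- samples
  set_groups(expression_dataset(vals), g, condition = "condition")
}

# Brute-force FAIME scoring: explicit per-sample, per-set loops.
faime_oracle <- function(values, set_list) {
  genes <- rownames(values)
  out <- matrix(NA_real_, length(set_list), ncol(values),
                dimnames = list(names(set_list), colnames(values)))
  for (j in seq_len(ncol(values))) {
    x <- values[, j]
    r <- rank(-x, ties.method = "average")
    w <- numeric(length(x))
    for (i in seq_along(x)) w[i] <- x[i] * exp(-(r[i] - 1) / length(x))
    names(w) <- genes
    for (s in seq_along(set_list)) {
      members <- intersect(set_list[[s]], genes)
      others <- setdiff(genes, members)
      msum <- 0; for (m in members) msum <- msum + w[[m]]
      osum <- 0; for (o in others) osum <- osum + w[[o]]
      out[s, j] <- msum / length(members) - osum / length(others)
    }
  }
  out
}

# Brute-force AUC: count all (control, condition) pairs, ties 1/2.
auc_oracle <- function(values, labels, condition) {
  pos <- values[labels == condition]
  neg <- values[labels != condition]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Upper hypergeometric tail by direct combinatorial summation.
hyper_tail_oracle <- function(k, K, N, n) {
  if (k <= 0) return(1)
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Upper hypergeometric tail by exhaustive enumeration of all C(N, n) draws.
hyper_enum_oracle <- function(k, K, N, n) {
  if (k <= 0) return(1)
  draws <- combn(N, n)
  hits <- colSums(draws <= K)   # universe 1..N with the set being 1..K
  mean(hits >= k)
}

# Classical pooled-variance two-sample t statistic (direct formula).
pooled_t_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  (mean(x2) - mean(x1)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Vectorized per-gene Welch t-test p-values (two-sided) for a dataset.
welch_p_by_gene <- function(dataset) {
  idx <- faimer:::group_indices(dataset)
  x1 <- dataset$values[, idx$control, drop = FALSE]
  x2 <- dataset$values[, idx$condition, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  2 * pt(-abs(t), df)
}

# Fixed-size gene-set collection over g1..g<n_genes>, sizes all `size`.
fixed_size_sets <- function(n_genes, n_sets, size, seed = 1L) {
  simulate_gene_sets(n_genes, n_sets, set_size_range = c(size, size),
                     seed = seed)
}
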