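#' SAM-style moderated difference statistic
#'
#' For each gene, `d = (mean_cond - mean_ctrl) / (s + s0)` where `s` is the
#' pooled two-sample scatter
#' `s = sqrt(((1/n1 + 1/n2) / (n1 + n2 - 2)) * (SS1 + SS2))`.
#' With `s0 = 0` and two groups this is the classical pooled-variance
#' two-sample t statistic. The exchangeability constant `s0` stabilizes `d`
#' for low-variance genes; `s0 = "auto"` picks the value minimizing the
#' coefficient of variation of the median absolute deviation of `d` across
#' genes binned by `s` quantiles (Tusher-style), searching the percentiles
#' of `s`.
#'
#' @param dataset an [expression_dataset()] with two groups (each >= 2
#'   samples).
#' @param s0 non-negative number, or `"auto"`.
#' @return a `data.frame` (gene, d, s, mean_diff) with the chosen `s0` as
#'   attribute `"s0"`.
#' @export
sam_statistics <- function(dataset, s0 = "auto") {
  idx <- group_indices(dataset)
  x1 <- dataset$values[, idx$control, drop = FALSE]
  x2 <- dataset$values[, idx$condition, drop = FALSE]
  comp <- sam_d_components(x1, x2)
  if (identical(s0, "auto")) {
    s0 <- tune_s0(comp$diff, comp$s)
    message(sprintf("SAM s0 (auto): %.6g", s0))
  }
  if (!is.numeric(s0) || length(s0) != 1L || s0 < 0)
    stop("`s0` must be \"auto\" or a single non-negative number")
  if (s0 == 0 && all(comp$s == 0))
    stop("zero scatter in every gene with s0 = 0; d undefined")
  d <- comp$diff / (comp$s + s0)
  res <- data.frame(gene = rownames(dataset$values), d = d, s = comp$s,
                    mean_diff = comp$diff, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "s0") <- s0
  res
}

# Mean difference and pooled scatter for two sample blocks (genes x n).
sam_d_components <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) * (ss1 + ss2))
  list(diff = m2 - m1, s = s)
}

# Tusher-style s0 search over percentiles of s: minimize the coefficient of
# variation of mad(d) across s-quantile bins.
tune_s0 <- function(diff, s, n_bins = 100L) {
  cand <- unique(stats::quantile(s, seq(0, 1, by = 0.05), names = FALSE))
  n_bins <- max(2L, min(n_bins, floor(length(s) / 20)))
  bins <- cut(rank(s, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  cv <- vapply(cand, function(a) {
    d <- diff / (s + a)
    v <- tapply(d, bins, stats::mad)
    if (mean(v) == 0) return(Inf)
    stats::sd(v) / mean(v)
  }, 0)
  cand[which.min(cv)]
}

#' Permutation-based FDR (q-values) for SAM statistics
#'
#' Permutes group labels, recomputes `d` for every gene under each
#' permutation, and estimates for each gene
#' `q(g) = median_b #\{|d_b| >= |d_obs(g)|\} / #\{|d_obs| >= |d_obs(g)|\}`,
#' capped at 1 and made monotone non-increasing in `|d|` by
#' cumulative-minimum smoothing (so q-value thresholds are coherent with
#' `|d|` thresholds). `n_perm = "exhaustive"` enumerates all distinct label
#' assignments (feasible up to 10,000).
#'
#' @param dataset an [expression_dataset()] with two groups.
#' @param d_obs observed per-gene `d` (from [sam_statistics()], same gene
#'   order as the dataset).
#' @param s0 the exchangeability constant used for `d_obs`.
#' @param n_perm number of Monte-Carlo label permutations (>= 50), or
#'   `"exhaustive"`.
#' @param seed RNG seed (ignored for exhaustive enumeration).
#' @return numeric vector of q-values in `[0, 1]`, same order as `d_obs`;
#'   the number of assignments enumerated is attribute `"n_perm_used"`.
#' @export
estimate_fdr_permutation <- function(dataset, d_obs, s0, n_perm = 200L,
                                     seed = 1L) {
  idx <- group_indices(dataset)
  n1 <- length(idx$control); n2 <- length(idx$condition)
  n <- n1 + n2
  x <- dataset$values[, c(idx$control, idx$condition), drop = FALSE]
  exhaustive <- identical(n_perm, "exhaustive")
  if (!exhaustive) {
    n_perm <- as.integer(n_perm)
    if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1 or \"exhaustive\"")
    if (n_perm < 50L)
      warning("n_perm < 50 gives unstable FDR estimates")
  }

  if (exhaustive) {
    if (choose(n, n1) > 10000)
      stop("exhaustive enumeration infeasible: ", choose(n, n1),
           " assignments (> 10,000)")
    assigns <- utils::combn(n, n1, simplify = FALSE)
    message(sprintf("exhaustive permutation FDR: %d label assignments",
                    length(assigns)))
  } else {
    assigns <- with_seed(seed, replicate(n_perm, sample(n, n1),
                                         simplify = FALSE))
  }

  abs_obs <- abs(d_obs)
  ord <- order(abs_obs)            # ascending |d|
  thr <- abs_obs[ord]
  m <- length(d_obs)
  obs_count <- m - findInterval(thr, thr, left.open = TRUE) # >= thr, ties incl.

  perm_counts <- vapply(assigns, function(g1) {
    comp <- sam_d_components(x[, g1, drop = FALSE],
                             x[, -g1, drop = FALSE])
    ad <- sort(abs(comp$diff / (comp$s + s0)))
    m - findInterval(thr, ad, left.open = TRUE)
  }, numeric(m))

  med <- apply(perm_counts, 1L, stats::median)
  q_sorted <- pmin(1, med / obs_count)
  # monotone non-increasing in |d|: walking from the least to the most
  # extreme gene, each q becomes the running minimum of the raw estimates
  # (cumulative-minimum smoothing), so |d| thresholds and q thresholds agree
  q_sorted <- cummin(q_sorted)
  q <- numeric(m)
  q[ord] <- q_sorted
  attr(q, "n_perm_used") <- length(assigns)
  q
}

#' Per-gene log2 mean difference and linear fold-change magnitude
#'
#' @param dataset an [expression_dataset()] with two groups.
#' @return `data.frame` (gene, mean_diff, fc): `mean_diff` is condition
#'   minus control on the log2 scale; `fc = 2^|mean_diff| >= 1` with the
#'   direction carried by the sign of `mean_diff`.
#' @export
fold_change <- function(dataset) {
  idx <- group_indices(dataset)
  m1 <- rowMeans(dataset$values[, idx$control, drop = FALSE])
  m2 <- rowMeans(dataset$values[, idx$condition, drop = FALSE])
  data.frame(gene = rownames(dataset$values), mean_diff = m2 - m1,
             fc = 2^abs(m2 - m1), stringsAsFactors = FALSE, row.names = NULL)
}

#' Call deregulated genes from a differential table
#'
#' `up` iff `mean_diff > 0 & fc > fc_threshold & q < q_threshold`
#' (strict inequalities at both gates); `down` symmetric; `none` otherwise.
#'
#' @param table `data.frame` with columns `gene`, `d`, `mean_diff`, `fc`,
#'   `q`.
#' @param fc_threshold linear fold-change gate (> 1).
#' @param q_threshold FDR gate in (0, 1).
#' @return the table with a `call` column; attributes `up_genes` /
#'   `down_genes` hold the called gene lists in decreasing `|d|` order.
#' @export
call_deregulated <- function(table, fc_threshold = 1.3, q_threshold = 0.01) {
  need <- c("gene", "d", "mean_diff", "fc", "q")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(fc_threshold) || fc_threshold <= 1)
    stop("fc_threshold must be > 1")
  if (!is.numeric(q_threshold) || q_threshold <= 0 || q_threshold >= 1)
    stop("q_threshold must be in (0, 1)")
  pass <- table$fc > fc_threshold & table$q < q_threshold
  call <- ifelse(pass & table$mean_diff > 0, "up",
                 ifelse(pass & table$mean_diff < 0, "down", "none"))
  table$call <- call
  ord <- order(-abs(table$d))
  attr(table, "up_genes") <- table$gene[ord][table$call[ord] == "up"]
  attr(table, "down_genes") <- table$gene[ord][table$call[ord] == "down"]
  table
}

#' Full differential-expression analysis
#'
#' [sam_statistics()] + [fold_change()] + [estimate_fdr_permutation()] +
#' [call_deregulated()], returning a complete differential table. The
#' `"cells"` preset gates at FDR < 1%, the `"mouse"` preset at FDR < 10%
#' (both FC > 1.3).
#'
#' @param dataset an [expression_dataset()] with two groups.
#' @param s0 see [sam_statistics()].
#' @param n_perm see [estimate_fdr_permutation()].
#' @param seed RNG seed for the permutations.
#' @param fc_threshold,q_threshold gates for [call_deregulated()];
#'   overridden by `preset`.
#' @param preset `NULL`, `"cells"` (q < 0.01) or `"mouse"` (q < 0.10).
#' @return a `differential_table` data.frame (gene, d, s, mean_diff, fc, q,
#'   call) with attributes `s0`, `up_genes`, `down_genes`.
#' @export
differential_analysis <- function(dataset, s0 = "auto", n_perm = 200L,
                                  seed = 1L, fc_threshold = 1.3,
                                  q_threshold = 0.01, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("cells", "mouse"))
    q_threshold <- if (preset == "cells") 0.01 else 0.10
    fc_threshold <- 1.3
  }
  stats <- sam_statistics(dataset, s0 = s0)
  fc <- fold_change(dataset)
  q <- estimate_fdr_permutation(dataset, stats$d, attr(stats, "s0"),
                                n_perm = n_perm, seed = seed)
  tab <- data.frame(gene = stats$gene, d = stats$d, s = stats$s,
                    mean_diff = fc$mean_diff, fc = fc$fc, q = as.numeric(q),
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- call_deregulated(tab, fc_threshold = fc_threshold,
                          q_threshold = q_threshold)
  attr(tab, "s0") <- attr(stats, "s0")
  class(tab) <- c("differential_table", "data.frame")
  tab
}
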