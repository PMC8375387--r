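#' Per-set two-group comparison of single-sample scores
#'
#' Welch unequal-variance t test of each set's scores between the control
#' and condition groups. Direction is the sign of (condition mean - control
#' mean); the "up-regulated in condition" list collects sets with positive
#' direction and `p < alpha` (the default is the two-sided p with a
#' directional post-filter; a one-sided `greater` mode is available).
#' Sets with zero score variance in both groups are untestable and are
#' excluded with a warning.
#'
#' @param scores a `set_score_matrix` with groups attached (>= 2 samples
#'   per group).
#' @param alternative `"two.sided"` (default) or `"greater"` (condition >
#'   control).
#' @param alpha significance threshold used for the up list (default
#'   0.05).
#' @return `data.frame` (set, t, df, p, direction, mean_diff); attribute
#'   `up_sets` holds the up-regulated set names.
#' @export
set_group_test <- function(scores, alternative = c("two.sided", "greater"),
                           alpha = 0.05) {
  stopifnot(inherits(scores, "set_score_matrix"))
  alternative <- match.arg(alternative)
  if (is.null(scores$groups)) stop("score matrix has no group assignment")
  g <- scores$groups
  i1 <- which(g == levels(g)[1L]); i2 <- which(g == levels(g)[2L])
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each group needs >= 2 samples")
  x1 <- scores$scores[, i1, drop = FALSE]
  x2 <- scores$scores[, i2, drop = FALSE]
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  untestable <- v1 == 0 & v2 == 0
  if (any(untestable))
    warning("excluded untestable set(s) with zero variance in both groups: ",
            paste(rownames(scores$scores)[untestable], collapse = ", "))
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- if (alternative == "two.sided") 2 * stats::pt(-abs(t_stat), df)
       else stats::pt(t_stat, df, lower.tail = FALSE)
  res <- data.frame(set = rownames(scores$scores), t = t_stat, df = df,
                    p = p, direction = sign(m2 - m1), mean_diff = m2 - m1,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[!untestable, , drop = FALSE]
  attr(res, "up_sets") <- res$set[res$direction > 0 & res$p < alpha]
  res
}

#' Cumulative hypergeometric overlap between two set lists
#'
#' Given two lists of set names drawn from a common universe of tested
#' sets, computes the upper-tail probability that a random list of size
#' `|list_b|` shares at least the observed number of members with
#' `list_a`: `p = sum_{j >= k} C(K, j) C(N-K, n-j) / C(N, n)`.
#'
#' @param list_a,list_b character vectors of set names, subsets of
#'   `universe`.
#' @param universe character vector of all set names eligible for both
#'   lists.
#' @return an `overlap_test` list: `universe_size`, `list_a_size`,
#'   `list_b_size`, `overlap`, `p`, `overlap_names`.
#' @export
overlap_hypergeometric <- function(list_a, list_b, universe) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  universe <- unique(universe)
  bad <- c(setdiff(list_a, universe), setdiff(list_b, universe))
  if (length(bad))
    stop("list member(s) not in universe: ", paste(bad, collapse = ", "))
  k <- length(intersect(list_a, list_b))
  K <- length(list_a); n <- length(list_b); N <- length(universe)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  structure(list(universe_size = N, list_a_size = K, list_b_size = n,
                 overlap = k, p = p,
                 overlap_names = intersect(list_a, list_b)),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap: %d of %d vs %d (universe %d), cumulative hypergeometric p = %.3g\n",
              x$overlap, x$list_a_size, x$list_b_size, x$universe_size, x$p))
  invisible(x)
}

#' Hierarchical-clustering leaf order for heatmap rendering
#'
#' Rows are z-scored (a constant row becomes zeros, with a warning), then
#' the chosen axis is clustered by average-linkage agglomeration on
#' Euclidean distances. The returned leaf order is deterministic for a
#' given input.
#'
#' @param mat numeric matrix (e.g. a set-score or expression submatrix),
#'   or a `set_score_matrix`.
#' @param axis `"rows"` or `"columns"`.
#' @return integer leaf order along the chosen axis; the `hclust` object
#'   is attached as attribute `"hclust"`.
#' @export
cluster_order <- function(mat, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  if (inherits(mat, "set_score_matrix")) mat <- mat$scores
  sds <- apply(mat, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant row(s) z-scored to zeros")
    sds[sds == 0] <- 1
  }
  z <- (mat - rowMeans(mat)) / sds
  obj <- if (axis == "rows") z else t(z)
  if (nrow(obj) < 2L) stop("need >= 2 items on the clustered axis")
  hc <- stats::hclust(stats::dist(obj, method = "euclidean"),
                      method = "average")
  structure(hc$order, hclust = hc)
}

#' Cross-condition log2 fold-change concordance
#'
#' Pearson correlation of two per-gene log2FC vectors on their shared
#' genes, with the two-sided t-transform p-value, plus (optionally) the
#' genes deregulated in the same direction in both analyses.
#'
#' @param fc_a,fc_b named numeric vectors of log2 fold changes.
#' @param calls_a,calls_b optional named character vectors of deregulation
#'   calls (`"up"`/`"down"`/`"none"`), e.g. the `call` column of a
#'   differential table named by gene.
#' @return a `concordance_result` list: `r`, `p`, `n_genes`,
#'   `common_deregulated`.
#' @export
logfc_concordance <- function(fc_a, fc_b, calls_a = NULL, calls_b = NULL) {
  shared <- intersect(names(fc_a), names(fc_b))
  if (length(shared) < 3L) stop("need >= 3 shared genes")
  a <- fc_a[shared]; b <- fc_b[shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in a fold-change vector")
  ct <- stats::cor.test(a, b, method = "pearson")
  common <- character(0)
  if (!is.null(calls_a) && !is.null(calls_b)) {
    cg <- intersect(names(calls_a), names(calls_b))
    common <- cg[(calls_a[cg] == "up" & calls_b[cg] == "up") |
                   (calls_a[cg] == "down" & calls_b[cg] == "down")]
  }
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 n_genes = length(shared), common_deregulated = common),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("log2FC concordance: r = %.3f (p = %.3g) over %d shared genes; %d commonly deregulated\n",
              x$r, x$p, x$n_genes, length(x$common_deregulated)))
  invisible(x)
}
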