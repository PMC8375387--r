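#' Rank-decayed expression weights for one sample
#'
#' The single-sample scoring kernel: within one sample's expression column,
#' genes are ranked descending (rank 1 = highest expression, ties get the
#' average rank) and weighted as `w(g) = x(g) * exp(-(r(g) - 1) / N)` with
#' `N` the number of genes. For non-negative expression the weight is
#' strictly decreasing in rank, so highly expressed genes dominate a set's
#' score. An alternative scheme `"rank_only"` uses `exp(-(r - 1) / N)`
#' without the expression factor.
#'
#' @param x numeric vector of per-gene log2 expression (>= 2 genes, all
#'   finite).
#' @param scheme `"exp_rank"` (default) or `"rank_only"`.
#' @return numeric vector of weights, same order/names as `x`.
#' @export
sample_rank_weights <- function(x, scheme = c("exp_rank", "rank_only")) {
  scheme <- match.arg(scheme)
  if (length(x) < 2L) stop("need >= 2 genes to rank")
  if (any(!is.finite(x))) stop("non-finite expression value(s)")
  r <- rank(-x, ties.method = "average")
  decay <- exp(-(r - 1) / length(x))
  if (scheme == "exp_rank") x * decay else decay
}

#' Single-sample gene-set scores (FAIME-style)
#'
#' Transforms a genes x samples matrix into a sets x samples score matrix.
#' Per sample, genes are rank-weighted ([sample_rank_weights()]) and each
#' set scores the difference between the mean weight of its member genes
#' and the mean weight of all non-member genes. Scores are column-local:
#' sample `j`'s scores depend only on column `j`. A higher score means the
#' set is, as a whole, more highly expressed (up-regulated) in that sample.
#'
#' @param dataset an [expression_dataset()] (log2 scale, post-filtering).
#' @param sets a [gene_set_collection()].
#' @param min_set_genes,max_set_genes size bounds applied to
#'   `|set ∩ measured genes|`; out-of-bounds sets are dropped with a
#'   warning (defaults 5 and 500).
#' @param weight_scheme passed to [sample_rank_weights()].
#' @return a `set_score_matrix`: list with `scores` (sets x samples
#'   matrix) and `groups` (inherited from the dataset, possibly `NULL`).
#' @export
faime_scores <- function(dataset, sets, min_set_genes = 5L,
                         max_set_genes = 500L,
                         weight_scheme = c("exp_rank", "rank_only")) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(sets, "gene_set_collection"))
  weight_scheme <- match.arg(weight_scheme)
  genes <- rownames(dataset$values)
  members <- lapply(sets$sets, intersect, genes)
  sz <- lengths(members)
  empty <- sz == 0L
  if (any(empty))
    warning("dropped set(s) with no measured genes: ",
            paste(names(sets)[empty], collapse = ", "))
  full <- sz == length(genes)
  if (any(full))
    stop("set(s) equal to the whole gene universe (empty complement): ",
         paste(names(sets)[full], collapse = ", "))
  in_bounds <- !empty & sz >= min_set_genes & sz <= max_set_genes
  if (any(!in_bounds & !empty))
    warning(sprintf("dropped %d set(s) outside size bounds [%d, %d]",
                    sum(!in_bounds & !empty), min_set_genes, max_set_genes))
  if (!any(in_bounds)) stop("no scorable sets after size filtering")
  members <- members[in_bounds]

  w <- apply(dataset$values, 2L, sample_rank_weights, scheme = weight_scheme)
  rownames(w) <- genes
  total <- colSums(w)
  n_genes <- length(genes)
  scores <- t(vapply(members, function(m) {
    msum <- colSums(w[m, , drop = FALSE])
    msum / length(m) - (total - msum) / (n_genes - length(m))
  }, numeric(ncol(w))))
  dimnames(scores) <- list(names(members), colnames(dataset$values))
  structure(list(scores = scores, groups = dataset$groups),
            class = "set_score_matrix")
}

#' @export
print.set_score_matrix <- function(x, ...) {
  cat(sprintf("set_score_matrix: %d sets x %d samples\n",
              nrow(x$scores), ncol(x$scores)))
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat(sprintf("  groups: %s\n",
                paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

# Restrict a score matrix to a subset of sets (names or indices).
subset_sets <- function(ssm, sets) {
  stopifnot(inherits(ssm, "set_score_matrix"))
  ssm$scores <- ssm$scores[sets, , drop = FALSE]
  ssm
}
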