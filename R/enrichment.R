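#' One-sided Fisher (hypergeometric) over-representation test
#'
#' Tests each gene set for over-representation of a gene list within a
#' universe. With `N` universe genes, `K` set members in the universe, `n`
#' list genes and `k` hits, the p-value is the upper hypergeometric tail
#' `P[X >= k]` — identical to a one-sided Fisher exact test on the 2x2
#' table. Sets overlapping the universe in fewer than `min_overlap_genes`
#' genes are excluded (and do not count toward the Benjamini-Hochberg `m`).
#'
#' @param gene_list character vector, a subset of `universe`.
#' @param universe character vector of background genes.
#' @param sets a [gene_set_collection()].
#' @param min_overlap_genes minimum `|set ∩ universe|` for a set to be
#'   tested (default 3).
#' @return `data.frame` (set, k, K, n, N, p, p_adj), sorted by `p`
#'   ascending.
#' @export
fisher_enrichment <- function(gene_list, universe, sets,
                              min_overlap_genes = 3L) {
  gene_list <- unique(gene_list)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(gene_list, universe)
  if (length(outside))
    stop("gene list not contained in universe: ",
         paste(utils::head(outside, 5L), collapse = ", "),
         if (length(outside) > 5L) ", ..." else "")
  N <- length(universe)
  n <- length(gene_list)
  in_univ <- lapply(sets$sets, intersect, universe)
  K <- lengths(in_univ)
  tested <- K >= min_overlap_genes
  if (any(!tested))
    message(sprintf("excluded %d set(s) with < %d genes in the universe",
                    sum(!tested), min_overlap_genes))
  if (!any(tested))
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  k <- vapply(in_univ[tested], function(m) length(intersect(m, gene_list)),
              0L)
  K <- K[tested]
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(set = names(sets)[tested], k = k, K = K, n = n, N = N,
                    p = p, p_adj = bh_adjust(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  res[order(res$p, res$set), , drop = FALSE]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Input order is preserved; `m` is the number of p-values supplied, so the
#' caller controls the correction universe.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
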