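#' Expression dataset container
#'
#' Bundles a genes x samples log2 expression matrix with optional per-cell
#' detection p-values, per-gene annotations and a two-group sample
#' assignment. All downstream stages (filtering, differential analysis,
#' single-sample scoring) consume this container. Expression is always held
#' on the log2 scale internally; linear-scale inputs are transformed at read
#' time (see [log2_transform()]).
#'
#' @param values numeric matrix, genes x samples, with unique non-empty
#'   rownames (gene identifiers) and colnames (sample identifiers). Log2
#'   units.
#' @param detection_p optional numeric matrix of detection p-values in
#'   `[0, 1]` with identical dimnames, or `NULL`.
#' @param annotations optional `data.frame` with columns `gene`, `symbol`,
#'   `chromosome`, `multi_mapped` (0/1) covering every gene, or `NULL`.
#' @param groups optional named factor (or character vector) mapping every
#'   sample to one of exactly two group labels; the second factor level is
#'   the "condition" group (knockdown, patient, knockout), or `NULL`.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `detection_p`, `annotations`, `groups`.
#' @export
expression_dataset <- function(values, detection_p = NULL, annotations = NULL,
                               groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifier(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifier(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !identical(dim(detection_p), dim(values)))
      stop("`detection_p` must be a matrix with the same shape as `values`")
    dimnames(detection_p) <- dimnames(values)
    if (anyNA(detection_p) || any(detection_p < 0 | detection_p > 1))
      stop("detection p-values must lie in [0, 1]")
  }
  ds <- structure(
    list(values = values, detection_p = detection_p,
         annotations = NULL, groups = NULL),
    class = "expression_dataset")
  if (!is.null(annotations)) ds <- set_annotations(ds, annotations)
  if (!is.null(groups)) ds <- set_groups(ds, groups)
  ds
}

#' Attach a two-group sample assignment
#'
#' @param dataset an [expression_dataset()].
#' @param groups named character vector or factor, `sample -> group label`.
#'   Every sample of the dataset must be assigned; no extra samples allowed.
#' @param condition optional label to treat as the condition (second) group.
#'   Defaults to the second level in sorted label order.
#' @return the dataset with `groups` attached as a named two-level factor
#'   (levels: control first, condition second).
#' @export
set_groups <- function(dataset, groups, condition = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  samples <- colnames(dataset$values)
  if (is.factor(groups)) {
    nm <- names(groups)
    groups <- as.character(groups)
    names(groups) <- nm
  }
  if (is.null(names(groups)))
    stop("`groups` must be named by sample identifier")
  unknown <- setdiff(names(groups), samples)
  if (length(unknown))
    stop("group assignment for unknown sample(s): ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(samples, names(groups))
  if (length(missing))
    stop("no group label for sample(s): ", paste(missing, collapse = ", "))
  groups <- groups[samples]
  labs <- sort(unique(groups))
  if (length(labs) != 2L)
    stop("exactly two group labels required, got: ",
         paste(labs, collapse = ", "))
  if (!is.null(condition)) {
    if (!condition %in% labs)
      stop("condition label '", condition, "' not among group labels")
    labs <- c(setdiff(labs, condition), condition)
  }
  dataset$groups <- factor(groups, levels = labs)
  names(dataset$groups) <- samples
  dataset
}

#' Attach per-gene annotations
#'
#' @param dataset an [expression_dataset()].
#' @param annotations `data.frame` with columns `gene`, `symbol`,
#'   `chromosome`, `multi_mapped`; must cover every gene of the dataset.
#' @return the dataset with annotations attached (rows aligned to genes).
#' @export
set_annotations <- function(dataset, annotations) {
  stopifnot(inherits(dataset, "expression_dataset"))
  need <- c("gene", "symbol", "chromosome", "multi_mapped")
  if (!is.data.frame(annotations) || !all(need %in% names(annotations)))
    stop("`annotations` must be a data.frame with columns: ",
         paste(need, collapse = ", "))
  genes <- rownames(dataset$values)
  missing <- setdiff(genes, annotations$gene)
  if (length(missing))
    stop("annotation missing for gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ..." else "")
  ann <- annotations[match(genes, annotations$gene), need, drop = FALSE]
  rownames(ann) <- genes
  ann$multi_mapped <- as.integer(ann$multi_mapped)
  dataset$annotations <- ann
  dataset
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  detection p-values: %s\n",
              if (is.null(x$detection_p)) "absent" else "present"))
  cat(sprintf("  annotations: %s\n",
              if (is.null(x$annotations)) "absent" else "present"))
  if (is.null(x$groups)) {
    cat("  groups: absent\n")
  } else {
    tab <- table(x$groups)
    cat(sprintf("  groups: %s\n",
                paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

# Keep a gene subset, carrying detection_p and annotations along.
subset_genes <- function(dataset, keep) {
  stopifnot(inherits(dataset, "expression_dataset"))
  dataset$values <- dataset$values[keep, , drop = FALSE]
  if (!is.null(dataset$detection_p))
    dataset$detection_p <- dataset$detection_p[keep, , drop = FALSE]
  if (!is.null(dataset$annotations))
    dataset$annotations <- dataset$annotations[keep, , drop = FALSE]
  dataset
}

# Column indices of the two groups; errors if groups are absent or a group
# used in a comparison has fewer than `min_per_group` samples.
group_indices <- function(dataset, min_per_group = 2L) {
  if (is.null(dataset$groups))
    stop("dataset has no group assignment; call set_groups() first")
  g <- dataset$groups
  idx <- list(control = which(g == levels(g)[1L]),
              condition = which(g == levels(g)[2L]))
  if (any(lengths(idx) < min_per_group))
    stop(sprintf("each group needs >= %d samples for a comparison (have %d, %d)",
                 min_per_group, length(idx$control), length(idx$condition)))
  idx
}
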