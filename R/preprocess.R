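#' Log2-transform a linear-scale dataset
#'
#' @param dataset an [expression_dataset()] holding linear-scale values
#'   (all `>= 0`).
#' @param offset non-negative constant added before taking log2.
#' @return the dataset with `values <- log2(values + offset)`.
#' @export
log2_transform <- function(dataset, offset = 0) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!is.numeric(offset) || length(offset) != 1L || offset < 0)
    stop("`offset` must be a single non-negative number")
  v <- dataset$values
  if (any(v < 0)) {
    bad <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at gene '%s', sample '%s'; linear input required",
                 rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
  }
  if (offset == 0 && any(v == 0))
    stop("zero values with offset 0 would give -Inf; use a positive offset")
  dataset$values <- log2(v + offset)
  message(sprintf("log2-transformed %d x %d matrix (offset = %g)",
                  nrow(v), ncol(v), offset))
  dataset
}

#' Detection (presence) filter
#'
#' Keeps the genes that are reliably detected: detection p-value below
#' `alpha` in every sample of at least one group. This mirrors the standard
#' DABG presence rule for expression arrays.
#'
#' @param dataset an [expression_dataset()] with `detection_p` and groups
#'   attached.
#' @param alpha detection p threshold (strict inequality), default 0.01.
#' @return the filtered dataset.
#' @export
apply_detection_filter <- function(dataset, alpha = 0.01) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$detection_p))
    stop("dataset has no detection p-values; skip this filter explicitly ",
         "(do not call apply_detection_filter) if none are available")
  idx <- group_indices(dataset, min_per_group = 1L)
  p <- dataset$detection_p
  ok1 <- rowSums(p[, idx$control, drop = FALSE] < alpha) ==
    length(idx$control)
  ok2 <- rowSums(p[, idx$condition, drop = FALSE] < alpha) ==
    length(idx$condition)
  keep <- ok1 | ok2
  message(sprintf("detection filter (p < %g in all samples of >= 1 group): removed %d of %d genes",
                  alpha, sum(!keep), length(keep)))
  subset_genes(dataset, keep)
}

#' Annotation-based gene filters
#'
#' Removes multi-mapped rows, removes rows on the X and Y chromosomes
#' (sex-linked expression would confound case/control contrasts), and
#' collapses rows sharing a gene symbol to the row with the highest mean
#' expression, so the final matrix has one row per unique symbol.
#'
#' @param dataset an [expression_dataset()] with annotations attached.
#' @return the filtered dataset.
#' @export
apply_annotation_filters <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$annotations))
    stop("dataset has no annotations; call set_annotations() first")
  ann <- dataset$annotations
  chrom <- tolower(ann$chromosome)
  sex <- chrom %in% c("x", "y", "chrx", "chry")
  multi <- ann$multi_mapped == 1L
  keep <- !sex & !multi
  n_sex <- sum(sex)
  n_multi <- sum(multi & !sex)
  dataset <- subset_genes(dataset, keep)
  ann <- dataset$annotations

  # collapse duplicate symbols: keep the row with the highest mean expression
  means <- rowMeans(dataset$values)
  ord <- order(-means)
  dup <- duplicated(ann$symbol[ord])
  keep2 <- logical(nrow(ann))
  keep2[ord[!dup]] <- TRUE
  n_collapsed <- sum(!keep2)
  if (n_collapsed > 0L) {
    collapsed <- unique(ann$symbol[!keep2])
    message(sprintf("collapsed %d duplicate-symbol row(s) (%d symbol(s): %s%s) keeping max-mean rows",
                    n_collapsed, length(collapsed),
                    paste(utils::head(collapsed, 5L), collapse = ", "),
                    if (length(collapsed) > 5L) ", ..." else ""))
  }
  message(sprintf("annotation filters: removed %d X/Y gene(s), %d multi-mapped, %d duplicate-symbol row(s)",
                  n_sex, n_multi, n_collapsed))
  subset_genes(dataset, keep2)
}

#' Standard preprocessing chain
#'
#' Detection filter (optional) followed by annotation filters. Gene filters
#' never alter the sample set or the group assignment.
#'
#' @param dataset an [expression_dataset()] with groups attached.
#' @param detection_alpha detection threshold; `NULL` (or a dataset without
#'   detection p-values plus `skip_detection = TRUE`) skips the filter.
#' @param skip_detection set `TRUE` to skip the detection filter explicitly
#'   when no detection p-values exist.
#' @return the filtered dataset.
#' @export
preprocess_dataset <- function(dataset, detection_alpha = 0.01,
                               skip_detection = FALSE) {
  if (!skip_detection)
    dataset <- apply_detection_filter(dataset, alpha = detection_alpha)
  if (!is.null(dataset$annotations))
    dataset <- apply_annotation_filters(dataset)
  dataset
}
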