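#' Gene set collection
#'
#' An ordered, named collection of gene sets (flat member lists, as carried
#' by GMT files). Set names are unique, every set is non-empty and members
#' within a set are unique.
#'
#' @param sets named list of character vectors (gene identifiers).
#' @param descriptions optional character vector of per-set descriptions,
#'   recycled from `""`.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop("`sets` must be a fully named list of character vectors")
  if (anyDuplicated(names(sets)))
    stop("duplicate set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(lengths(sets) == 0L))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  dup <- vapply(sets, anyDuplicated, 0L) > 0L
  if (any(dup)) {
    warning("removed duplicate genes within set(s): ",
            paste(names(sets)[dup], collapse = ", "))
    sets[dup] <- lapply(sets[dup], unique)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(x$sets[i], x$descriptions[i])
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d, median %g)\n",
              length(x$sets), min(sz), max(sz), stats::median(sz)))
  invisible(x)
}
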