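#' Read a genes x samples expression matrix from TSV
#'
#' First row is the sample header, first column the gene identifiers, body
#' numeric. Linear-scale inputs are log2-transformed on read so the internal
#' scale is always log2. Missing values are a hard error (microarray
#' summaries are complete; no imputation is attempted).
#'
#' @param path path to a tab-separated file.
#' @param scale `"log2"` (default) or `"linear"`; linear values are
#'   transformed via [log2_transform()] with `offset`.
#' @param offset non-negative offset used only when `scale = "linear"`.
#' @return a partial [expression_dataset()] (no groups/annotations yet).
#' @export
read_expression_matrix <- function(path, scale = c("log2", "linear"),
                                   offset = 0) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty expression file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L || nrow(raw) < 1L)
    stop("expression file needs a gene column and >= 1 sample column")
  genes <- raw[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                  dimnames = list(genes, colnames(body))))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric cell '%s' at row %d (gene '%s'), column %d (sample '%s')",
      body[bad[1L], bad[2L]], bad[1L], genes[bad[1L]], bad[2L],
      colnames(body)[bad[2L]]))
  }
  ds <- expression_dataset(vals)
  if (scale == "linear") ds <- log2_transform(ds, offset = offset)
  ds
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()] (log2 scale on both sides).
#'
#' @param dataset an [expression_dataset()].
#' @param path output path.
#' @param what `"values"` or `"detection_p"`.
#' @export
write_expression_matrix <- function(dataset, path, what = c("values",
                                                            "detection_p")) {
  what <- match.arg(what)
  m <- dataset[[what]]
  if (is.null(m)) stop("dataset has no ", what)
  df <- data.frame(gene = rownames(m),
                   format_num(m, as_matrix = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: `name TAB description TAB gene TAB gene ...`.
#' Duplicate genes within a set are removed with a warning; duplicate set
#' names or lines with fewer than three fields are errors.
#'
#' @param path path to a GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample -> group assignment and attach it to a dataset
#'
#' Two-column TSV (`sample TAB group`, no header required; a header line
#' `sample<TAB>group` is tolerated). Row order in the file is irrelevant.
#'
#' @param path path to the two-column TSV.
#' @param dataset the [expression_dataset()] to attach groups to.
#' @param condition optional condition-group label (see [set_groups()]).
#' @return the dataset with groups attached.
#' @export
read_sample_groups <- function(path, dataset, condition = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  if (ncol(tab) != 2L) stop("group file must have exactly 2 columns")
  if (identical(tolower(unlist(tab[1L, ])), c("sample", "group")))
    tab <- tab[-1L, , drop = FALSE]
  g <- tab[[2L]]
  names(g) <- tab[[1L]]
  ds <- set_groups(dataset, g, condition = condition)
  tabg <- table(ds$groups)
  message(sprintf("attached %d samples in %d groups: %s", length(g),
                  length(tabg),
                  paste(sprintf("%s (n=%d)", names(tabg), tabg),
                        collapse = ", ")))
  ds
}

#' Read a gene annotation table and attach it to a dataset
#'
#' Four-column TSV with header `gene, symbol, chromosome, multi_mapped`
#' (multi_mapped in \{0, 1\}).
#'
#' @param path path to the annotation TSV.
#' @param dataset the [expression_dataset()] to attach annotations to.
#' @return the dataset with annotations attached.
#' @export
read_annotations <- function(path, dataset) {
  if (!file.exists(path)) stop("no such file: ", path)
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  set_annotations(dataset, ann)
}

#' Write a result table to TSV
#'
#' Tab-separated with a header row; numeric columns rendered with at least
#' six significant digits; rows written in input order. Empty tables are an
#' error (a result file with only a header is more often a pipeline bug
#' than a result).
#'
#' @param records a non-empty `data.frame`.
#' @param path output path.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records)) records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("refusing to write an empty result table")
  out <- records
  num <- vapply(out, is.numeric, TRUE) & !vapply(out, is.integer, TRUE)
  out[num] <- lapply(out[num], format_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Render numerics with 8 significant digits ("%.8g"), enough for 1e-6
# round-trips, without scientific-notation surprises in integers.
format_num <- function(x, as_matrix = FALSE) {
  if (as_matrix) {
    out <- apply(x, 2L, function(col) sprintf("%.12g", col))
    rownames(out) <- rownames(x)
    return(out)
  }
  sprintf("%.8g", x)
}
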