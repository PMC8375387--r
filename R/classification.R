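#' PCA of a set-score matrix
#'
#' Principal components of the samples in set-score space, restricted to a
#' candidate set list. By default each set's scores are z-scored across
#' samples first (sets have heterogeneous scales); raw-covariance mode via
#' `standardize = FALSE`. Each component's sign is fixed deterministically:
#' if groups are attached, the component is oriented so the condition-group
#' mean coordinate is >= the control-group mean (ties: the largest-loading
#' set gets a positive loading); without groups the largest-loading rule
#' applies.
#'
#' @param scores a `set_score_matrix`.
#' @param set_names optional subset of set names to use (default: all).
#' @param standardize z-score each set across samples before PCA (default
#'   `TRUE`).
#' @return a `pca_scores` list: `coordinates` (samples x components),
#'   `explained_variance` (fractions, non-increasing), `rotation`
#'   (sets x components), `center`, `groups`.
#' @export
pca_transform <- function(scores, set_names = NULL, standardize = TRUE) {
  stopifnot(inherits(scores, "set_score_matrix"))
  if (!is.null(set_names)) scores <- subset_sets(scores, set_names)
  x <- t(scores$scores)                      # samples x sets
  if (nrow(x) < 3L) stop("need >= 3 samples for PCA")
  if (ncol(x) < 2L) stop("need >= 2 sets for PCA")
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " constant set(s) scaled to zeros")
      sds[sds == 0] <- 1
    }
    x <- scale(x, center = TRUE, scale = sds)
  }
  pc <- stats::prcomp(x, center = !standardize, scale. = FALSE)
  coords <- pc$x
  rot <- pc$rotation
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  g <- scores$groups
  for (j in seq_len(ncol(coords))) {
    flip <- FALSE
    if (!is.null(g)) {
      dmean <- mean(coords[g == levels(g)[2L], j]) -
        mean(coords[g == levels(g)[1L], j])
      if (dmean < 0) flip <- TRUE
      else if (dmean == 0) flip <- rot[which.max(abs(rot[, j])), j] < 0
    } else {
      flip <- rot[which.max(abs(rot[, j])), j] < 0
    }
    if (flip) {
      coords[, j] <- -coords[, j]
      rot[, j] <- -rot[, j]
    }
  }
  structure(list(coordinates = coords, explained_variance = ev,
                 rotation = rot,
                 center = if (standardize) attr(x, "scaled:center")
                          else pc$center,
                 groups = g),
            class = "pca_scores")
}

#' Group-separation test on one principal component
#'
#' Welch two-sided t test comparing the two groups' coordinates on the
#' chosen component.
#'
#' @param pca a `pca_scores` object (from [pca_transform()] with groups).
#' @param component component index (1-based).
#' @return list with `t`, `df`, `p`.
#' @export
pc_separation_test <- function(pca, component = 2L) {
  stopifnot(inherits(pca, "pca_scores"))
  if (is.null(pca$groups)) stop("PCA object carries no group assignment")
  if (component > ncol(pca$coordinates))
    stop("component ", component, " not available")
  v <- pca$coordinates[, component]
  g <- pca$groups
  x1 <- v[g == levels(g)[1L]]; x2 <- v[g == levels(g)[2L]]
  if (length(x1) < 2L || length(x2) < 2L)
    stop("each group needs >= 2 samples")
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
    if (mean(x1) == mean(x2)) return(list(t = 0, df = NA_real_, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(x2, x1, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' ROC curve and AUC for a scalar score
#'
#' AUC is the Mann-Whitney probability that a random condition sample
#' scores above a random control sample, ties counted 1/2 — computed by the
#' rank identity and therefore exactly equal to pair counting. ROC points
#' are generated from every distinct threshold.
#'
#' @param values numeric per-sample scores.
#' @param labels group label per sample (two levels).
#' @param condition the label treated as positive; defaults to the second
#'   factor level of `labels`.
#' @return a `roc_result` list: `auc`, `roc` (data.frame with `threshold`,
#'   `fpr`, `tpr`).
#' @export
roc_auc <- function(values, labels, condition = NULL) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("both classes must be present")
  if (is.null(condition)) condition <- levels(labels)[nlevels(labels)]
  pos <- labels == condition
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(values)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(values), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(values[pos] >= t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(values[!pos] >= t) / n_neg, 0)
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  structure(list(auc = auc, roc = roc), class = "roc_result")
}

#' Random-gene-set resampling null for classification power
#'
#' Asks whether a candidate set list separates cohorts better than random
#' set lists of the same size. For each of `B` draws, `candidate_size` set
#' names are sampled uniformly without replacement from the sets common to
#' all cohorts; for every cohort the draw's scores are PCA-transformed and
#' the designated component's AUC computed; the draw's statistic is the
#' mean AUC across cohorts. The right-tailed p uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, so it is never zero.
#'
#' @param cohorts a single `set_score_matrix` or a list of them (full
#'   collections, all sets scored), each with groups attached.
#' @param candidate_sets character vector of candidate set names (present
#'   in every cohort).
#' @param component PC index used for classification (default 2).
#' @param B number of random draws (default 1000).
#' @param seed RNG seed.
#' @param standardize passed to [pca_transform()].
#' @return a `resampling_result` list: `observed` (mean AUC across
#'   cohorts), `per_cohort_auc`, `null_aucs` (length `B`), `p_right`, `B`.
#' @export
resample_random_sets <- function(cohorts, candidate_sets, component = 2L,
                                 B = 1000L, seed = 1L, standardize = TRUE) {
  if (inherits(cohorts, "set_score_matrix")) cohorts <- list(cohorts)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be >= 1")
  pool <- Reduce(intersect, lapply(cohorts, function(c) rownames(c$scores)))
  missing <- setdiff(candidate_sets, pool)
  if (length(missing))
    stop("candidate set(s) not scored in every cohort: ",
         paste(missing, collapse = ", "))
  size <- length(candidate_sets)
  if (size > length(pool))
    stop("candidate_size exceeds the number of available sets")
  cohort_auc <- function(set_names) {
    vapply(cohorts, function(co) {
      pc <- pca_transform(co, set_names = set_names,
                          standardize = standardize)
      v <- pc$coordinates[, component]
      roc_auc(v, co$groups)$auc
    }, 0)
  }
  per_cohort <- cohort_auc(candidate_sets)
  observed <- mean(per_cohort)
  null_aucs <- with_seed(seed, vapply(seq_len(B), function(b) {
    mean(cohort_auc(sample(pool, size)))
  }, 0))
  p_right <- (1 + sum(null_aucs >= observed)) / (B + 1)
  structure(list(observed = observed, per_cohort_auc = per_cohort,
                 null_aucs = null_aucs, p_right = p_right, B = B,
                 component = component, candidate_size = size),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("resampling null (B = %d, %d sets, PC%d): observed mean AUC = %.3f, right-tailed p = %.4g\n",
              x$B, x$candidate_size, x$component, x$observed, x$p_right))
  invisible(x)
}
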