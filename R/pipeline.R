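#' Derivation workflow: deregulated genes and candidate mediated sets
#'
#' Runs the knockdown-vs-control derivation contrast end to end:
#' preprocessing (detection + annotation filters where available),
#' SAM-style differential analysis with permutation FDR, deregulation
#' calls, and Fisher/BH over-representation of the up- and down-regulated
#' gene lists against a set collection. The candidate "mediated" list is
#' the sets enriched among down-regulated genes at `p_adj < alpha_adj`
#' (a knockdown's down-regulated genes mark the processes the targeted
#' regulator sustains).
#'
#' @param dataset an [expression_dataset()] with groups attached
#'   (condition = knockdown).
#' @param sets a [gene_set_collection()].
#' @param fc_threshold,q_threshold deregulation gates (defaults 1.3,
#'   0.01).
#' @param n_perm,seed permutation-FDR settings.
#' @param alpha_adj BH-adjusted significance line for enrichment (default
#'   0.05).
#' @param min_overlap_genes minimum set/universe overlap for enrichment.
#' @param detection_alpha,skip_detection preprocessing controls.
#' @param s0 SAM exchangeability constant (default `"auto"`).
#' @return a `derivation_result` list: `table` (differential table),
#'   `up_genes`, `down_genes`, `enrichment_up`, `enrichment_down`,
#'   `candidate_sets`, `provenance`.
#' @export
run_derivation <- function(dataset, sets, fc_threshold = 1.3,
                           q_threshold = 0.01, n_perm = 200L, seed = 1L,
                           alpha_adj = 0.05, min_overlap_genes = 3L,
                           detection_alpha = 0.01, skip_detection = FALSE,
                           s0 = "auto") {
  dataset <- preprocess_dataset(dataset, detection_alpha = detection_alpha,
                                skip_detection = skip_detection ||
                                  is.null(dataset$detection_p))
  tab <- differential_analysis(dataset, s0 = s0, n_perm = n_perm,
                               seed = seed, fc_threshold = fc_threshold,
                               q_threshold = q_threshold)
  up <- attr(tab, "up_genes"); down <- attr(tab, "down_genes")
  universe <- tab$gene
  enr <- lapply(list(up = up, down = down), function(lst) {
    if (!length(lst)) return(NULL)
    fisher_enrichment(lst, universe, sets,
                      min_overlap_genes = min_overlap_genes)
  })
  candidates <- if (is.null(enr$down)) character(0) else
    enr$down$set[enr$down$p_adj < alpha_adj]
  message(sprintf("derivation: %d up, %d down genes; %d candidate set(s) at p_adj < %g",
                  length(up), length(down), length(candidates), alpha_adj))
  structure(list(table = tab, up_genes = up, down_genes = down,
                 enrichment_up = enr$up, enrichment_down = enr$down,
                 candidate_sets = candidates,
                 provenance = pipeline_provenance(
                   seed = seed, fc_threshold = fc_threshold,
                   q_threshold = q_threshold, n_perm = n_perm,
                   alpha_adj = alpha_adj)),
            class = "derivation_result")
}

#' Cohort-validation workflow: overlap, PCA/AUC and resampling null
#'
#' For each disease/control cohort: score all sets per sample
#' ([faime_scores()]), find the sets up-regulated in the condition group
#' ([set_group_test()]), and test their overlap with the candidate list by
#' the cumulative hypergeometric tail over the universe of sets scored in
#' the cohort. The classification set list — by default the candidates
#' found up-regulated ("mediated") in every cohort — is then assessed by
#' PCA of the set-score matrix, the designated component's group-separation
#' t test and AUC, and the random-set resampling null computed across all
#' cohorts jointly.
#'
#' @param cohorts one [expression_dataset()] or a list of them, each with
#'   groups attached (condition = patients).
#' @param sets a [gene_set_collection()] (full collection; the resampling
#'   null draws from it).
#' @param candidate_sets character vector of candidate set names from the
#'   derivation contrast.
#' @param alpha per-set t-test significance for the up-regulated list.
#' @param component designated PC for classification (default 2).
#' @param B resampling draws (default 1000).
#' @param seed RNG seed for the resampling.
#' @param use_overlap if `TRUE` (default) classify on candidates
#'   up-regulated in every cohort; if `FALSE`, on all scored candidates.
#' @param alternative sidedness of the per-set t test.
#' @param min_set_genes,max_set_genes scoring size bounds.
#' @param standardize passed to [pca_transform()].
#' @return a `discrimination_report` list: `per_cohort` (scores, set
#'   tests, up list, overlap test, mediated sets, heatmap order, PCA, PC
#'   test, AUC), `classification_sets`, `resampling`, `provenance`. When
#'   the classification list has fewer than 2 sets, classification and
#'   resampling are skipped (overlap results are still reported).
#' @export
run_cohort_validation <- function(cohorts, sets, candidate_sets,
                                  alpha = 0.05, component = 2L, B = 1000L,
                                  seed = 1L, use_overlap = TRUE,
                                  alternative = "two.sided",
                                  min_set_genes = 5L, max_set_genes = 500L,
                                  standardize = TRUE) {
  if (inherits(cohorts, "expression_dataset")) cohorts <- list(cohorts)
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort_", seq_along(cohorts))
  if (!length(candidate_sets)) stop("empty candidate set list")

  per_cohort <- lapply(names(cohorts), function(nm) {
    ds <- cohorts[[nm]]
    ssm <- faime_scores(ds, sets, min_set_genes = min_set_genes,
                        max_set_genes = max_set_genes)
    sgt <- set_group_test(ssm, alternative = alternative, alpha = alpha)
    up <- attr(sgt, "up_sets")
    universe <- sgt$set
    cand_here <- intersect(candidate_sets, universe)
    ov <- overlap_hypergeometric(cand_here, up, universe)
    mediated <- ov$overlap_names
    heat_order <- if (length(mediated) >= 2L)
      cluster_order(subset_sets(ssm, mediated), axis = "rows") else
      seq_along(mediated)
    list(name = nm, scores = ssm, set_tests = sgt, up_sets = up,
         overlap = ov, mediated_sets = mediated, heatmap_order = heat_order)
  })
  names(per_cohort) <- names(cohorts)

  scored_everywhere <- Reduce(intersect, lapply(per_cohort, function(pc)
    rownames(pc$scores$scores)))
  classification_sets <- if (use_overlap)
    Reduce(intersect, lapply(per_cohort, `[[`, "mediated_sets")) else
    intersect(candidate_sets, scored_everywhere)

  resampling <- NULL
  if (length(classification_sets) >= 2L) {
    for (nm in names(per_cohort)) {
      pc <- pca_transform(per_cohort[[nm]]$scores,
                          set_names = classification_sets,
                          standardize = standardize)
      per_cohort[[nm]]$pca <- pc
      per_cohort[[nm]]$pc_test <- pc_separation_test(pc, component)
      per_cohort[[nm]]$auc <- roc_auc(pc$coordinates[, component],
                                      pc$groups)
    }
    resampling <- resample_random_sets(
      lapply(per_cohort, `[[`, "scores"), classification_sets,
      component = component, B = B, seed = seed,
      standardize = standardize)
  } else {
    message("classification skipped: fewer than 2 classification sets (overlap p-values still reported)")
  }
  structure(list(per_cohort = per_cohort,
                 classification_sets = classification_sets,
                 resampling = resampling,
                 provenance = pipeline_provenance(
                   seed = seed, alpha = alpha, component = component,
                   B = B, use_overlap = use_overlap)),
            class = "discrimination_report")
}

#' Cross-condition concordance workflow
#'
#' Runs the mouse-style cross-condition check: per-dataset differential
#' analysis at relaxed gates (defaults FDR < 10%, FC > 1.3), Pearson
#' correlation of the two log2 fold-change profiles over the shared gene
#' universe, the list of genes deregulated in the same direction in both
#' conditions, and a hierarchical-clustering row order for the
#' common-gene heatmap across the pooled samples.
#'
#' @param dataset_a,dataset_b two [expression_dataset()]s with groups,
#'   sharing (part of) a gene universe.
#' @param fc_threshold,q_threshold deregulation gates (mouse preset
#'   defaults: 1.3, 0.10).
#' @param n_perm,seed permutation-FDR settings.
#' @param s0 SAM exchangeability constant.
#' @return a `cross_condition_result` list: `table_a`, `table_b`,
#'   `concordance` (a `concordance_result`), `heatmap_order`,
#'   `provenance`.
#' @export
run_cross_condition <- function(dataset_a, dataset_b, fc_threshold = 1.3,
                                q_threshold = 0.10, n_perm = 200L,
                                seed = 1L, s0 = "auto") {
  shared <- intersect(rownames(dataset_a$values), rownames(dataset_b$values))
  if (!length(shared)) stop("datasets share no genes")
  run_one <- function(ds, stream) {
    differential_analysis(ds, s0 = s0, n_perm = n_perm,
                          seed = child_seed(seed, stream),
                          fc_threshold = fc_threshold,
                          q_threshold = q_threshold)
  }
  tab_a <- run_one(dataset_a, 1L)
  tab_b <- run_one(dataset_b, 2L)
  fc_a <- stats::setNames(tab_a$mean_diff, tab_a$gene)
  fc_b <- stats::setNames(tab_b$mean_diff, tab_b$gene)
  conc <- logfc_concordance(fc_a, fc_b,
                            calls_a = stats::setNames(tab_a$call, tab_a$gene),
                            calls_b = stats::setNames(tab_b$call, tab_b$gene))
  common <- conc$common_deregulated
  heat <- NULL
  if (length(common) >= 2L) {
    pooled <- cbind(dataset_a$values[common, , drop = FALSE],
                    dataset_b$values[common, , drop = FALSE])
    heat <- cluster_order(pooled, axis = "rows")
  }
  structure(list(table_a = tab_a, table_b = tab_b, concordance = conc,
                 heatmap_order = heat,
                 provenance = pipeline_provenance(
                   seed = seed, fc_threshold = fc_threshold,
                   q_threshold = q_threshold, n_perm = n_perm)),
            class = "cross_condition_result")
}

# Seed + parameter record attached to every workflow result.
pipeline_provenance <- function(...) {
  c(list(package = "faimer",
         version = as.character(utils::packageVersion("faimer"))),
    list(...))
}
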