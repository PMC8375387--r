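#' Simulation configuration for two-group microarray-like datasets
#'
#' Defines the generative model used throughout the test bench: per-gene
#' Gaussian log2 expression with gene-specific baselines and SDs, an
#' additive group effect planted in designated gene sets, a two-component
#' detection p-value model, and annotation quirks (duplicate symbols,
#' multi-mapped probes, sex-chromosome genes) so every filtering rule is
#' observable. Defaults emulate a small two-group array cohort (9 controls
#' vs 8 cases, ~2000 genes) with moderate per-gene noise.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group integer pair `(n_control, n_condition)`.
#' @param baseline_mean_range log2 interval for per-gene baseline means.
#' @param gene_sd_range log2 interval for per-gene residual SDs.
#' @param delta additive log2 shift applied to affected genes in the
#'   condition group (may be negative, e.g. knockdown-style down-shifts).
#' @param frac_affected_in_set fraction of each planted set's genes that
#'   receive `delta`.
#' @param silent_fraction fraction of genes with uniform (undetected)
#'   detection p-values in every sample; the rest draw Beta(0.1, 10).
#' @param sex_chrom_fraction fraction of genes annotated to chromosome X/Y.
#' @param multimap_fraction fraction of genes flagged multi-mapped.
#' @param dup_symbol_fraction fraction of genes given a symbol duplicating
#'   another gene's (independent expression rows, so the collapse rule is
#'   exercised).
#' @param seed integer RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000L,
                              n_samples_per_group = c(9L, 8L),
                              baseline_mean_range = c(4, 10),
                              gene_sd_range = c(0.2, 0.6),
                              delta = 1.0,
                              frac_affected_in_set = 1.0,
                              silent_fraction = 0.05,
                              sex_chrom_fraction = 0.04,
                              multimap_fraction = 0.02,
                              dup_symbol_fraction = 0.02,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_group = as.integer(n_samples_per_group),
              baseline_mean_range = baseline_mean_range,
              gene_sd_range = gene_sd_range,
              delta = delta,
              frac_affected_in_set = frac_affected_in_set,
              silent_fraction = silent_fraction,
              sex_chrom_fraction = sex_chrom_fraction,
              multimap_fraction = multimap_fraction,
              dup_symbol_fraction = dup_symbol_fraction,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 1L, length(cfg$n_samples_per_group) == 2L,
            all(cfg$n_samples_per_group >= 1L),
            is.finite(cfg$delta),
            cfg$frac_affected_in_set >= 0, cfg$frac_affected_in_set <= 1,
            cfg$silent_fraction >= 0, cfg$silent_fraction <= 1,
            cfg$sex_chrom_fraction >= 0, cfg$sex_chrom_fraction <= 1,
            cfg$multimap_fraction >= 0, cfg$multimap_fraction <= 1)
  structure(cfg, class = "simulation_config")
}

#' Simulate a gene-set collection
#'
#' Set members are drawn uniformly without replacement within each set
#' (overlap between sets is allowed); set sizes are uniform on
#' `set_size_range`.
#'
#' @param n_genes size of the gene universe (`g1 ... g<n>`).
#' @param n_sets number of sets.
#' @param set_size_range integer interval of set sizes, within
#'   `[2, n_genes]`.
#' @param seed RNG seed.
#' @param gene_ids optional explicit gene universe (defaults to
#'   `g1..g<n_genes>`).
#' @return a [gene_set_collection()].
#' @export
simulate_gene_sets <- function(n_genes, n_sets, set_size_range = c(10L, 50L),
                               seed = 1L, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n_genes))
  lo <- as.integer(set_size_range[1L]); hi <- as.integer(set_size_range[2L])
  if (lo < 2L || hi > length(gene_ids) || lo > hi)
    stop("infeasible set_size_range: must lie within [2, n_genes]")
  with_seed(seed, {
    sizes <- if (lo == hi) rep(lo, n_sets) else
      sample(lo:hi, n_sets, replace = TRUE)
    sets <- lapply(sizes, function(k) sample(gene_ids, k))
    names(sets) <- sprintf("set%03d", seq_len(n_sets))
    gene_set_collection(sets,
                        descriptions = sprintf("simulated set of %d genes",
                                               sizes))
  })
}

#' Simulate a two-group expression dataset with planted set effects
#'
#' `expression(g, s) = baseline(g) + effect(g) * 1[s in condition] + eps`,
#' `eps ~ N(0, sd(g))`; `effect(g) = delta` for a `frac_affected_in_set`
#' share of each planted set's genes and 0 otherwise. Detection p-values
#' follow a two-component model (Beta(0.1, 10) for expressed genes,
#' Uniform(0, 1) in every sample for a `silent_fraction` of genes).
#' Annotations plant duplicate symbols, multi-mapped flags and X/Y labels
#' at the configured fractions.
#'
#' @param cfg a [simulation_config()].
#' @param sets a [gene_set_collection()] over the same gene universe.
#' @param planted_sets names of sets receiving the `delta` shift (at most
#'   `length(sets)`); default none.
#' @return a list: `dataset` (complete [expression_dataset()]),
#'   `planted_sets`, `affected_genes`.
#' @export
simulate_dataset <- function(cfg, sets = NULL, planted_sets = character()) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (length(planted_sets)) {
    if (is.null(sets)) stop("planted sets given but no collection supplied")
    missing <- setdiff(planted_sets, names(sets))
    if (length(missing))
      stop("planted set(s) not in collection: ",
           paste(missing, collapse = ", "))
  }
  n_g <- cfg$n_genes
  n1 <- cfg$n_samples_per_group[1L]
  n2 <- cfg$n_samples_per_group[2L]
  genes <- paste0("g", seq_len(n_g))
  samples <- c(paste0("ctrl_", seq_len(n1)), paste0("cond_", seq_len(n2)))

  with_seed(cfg$seed, {
    baseline <- stats::runif(n_g, cfg$baseline_mean_range[1L],
                             cfg$baseline_mean_range[2L])
    sds <- stats::runif(n_g, cfg$gene_sd_range[1L], cfg$gene_sd_range[2L])

    effect <- numeric(n_g)
    names(effect) <- genes
    affected <- character(0)
    for (nm in planted_sets) {
      members <- intersect(sets$sets[[nm]], genes)
      k <- max(1L, round(cfg$frac_affected_in_set * length(members)))
      if (cfg$frac_affected_in_set == 0) k <- 0L
      if (k > 0L) {
        hit <- sample(members, k)
        effect[hit] <- cfg$delta
        affected <- union(affected, hit)
      }
    }

    vals <- baseline +
      matrix(stats::rnorm(n_g * (n1 + n2), 0, sds), nrow = n_g) # recycles sds by row
    vals[, (n1 + 1):(n1 + n2)] <- vals[, (n1 + 1):(n1 + n2)] + effect
    dimnames(vals) <- list(genes, samples)

    silent <- stats::runif(n_g) < cfg$silent_fraction
    detp <- matrix(0, n_g, n1 + n2, dimnames = dimnames(vals))
    n_exp <- sum(!silent)
    if (n_exp) detp[!silent, ] <- stats::rbeta(n_exp * (n1 + n2), 0.1, 10)
    if (any(silent)) detp[silent, ] <- stats::runif(sum(silent) * (n1 + n2))

    symbol <- paste0("SYM", seq_len(n_g))
    n_dup <- round(cfg$dup_symbol_fraction * n_g)
    if (n_dup > 0L && n_g >= 2L) {
      dup_rows <- sample(n_g, n_dup)
      donor <- sample(setdiff(seq_len(n_g), dup_rows), n_dup, replace = TRUE)
      symbol[dup_rows] <- symbol[donor]
    }
    chrom <- sample(paste0("chr", 1:19), n_g, replace = TRUE)
    n_sex <- round(cfg$sex_chrom_fraction * n_g)
    if (n_sex > 0L)
      chrom[sample(n_g, n_sex)] <- sample(c("chrX", "chrY"), n_sex,
                                          replace = TRUE)
    multi <- as.integer(stats::runif(n_g) < cfg$multimap_fraction)
    ann <- data.frame(gene = genes, symbol = symbol, chromosome = chrom,
                      multi_mapped = multi, stringsAsFactors = FALSE)

    groups <- c(rep("control", n1), rep("condition", n2))
    names(groups) <- samples
    ds <- expression_dataset(vals, detection_p = detp, annotations = ann)
    ds <- set_groups(ds, groups, condition = "condition")
    list(dataset = ds, planted_sets = planted_sets,
         affected_genes = affected)
  })
}

#' Paired-condition log2 fold-change generator
#'
#' Generates two per-gene log2FC vectors sharing a common effect component:
#' `fcA = s + uA + eA`, `fcB = s + uB + eB` with `s ~ N(0, shared_sd^2)`,
#' `u ~ N(0, private_sd^2)`, `e ~ N(0, noise_sd^2)`, all independent. The
#' expected Pearson correlation between the two vectors is
#' `shared_sd^2 / (shared_sd^2 + private_sd^2 + noise_sd^2)`, which makes
#' the generator a closed-form target for cross-condition concordance
#' checks.
#'
#' @param n_genes number of genes (>= 10).
#' @param shared_sd SD of the shared effect component (log2 units).
#' @param private_sd SD of each condition's independent component.
#' @param noise_sd SD of per-gene estimation noise.
#' @param seed RNG seed.
#' @return a list with named numeric vectors `fc_a`, `fc_b` and
#'   `expected_r`.
#' @export
simulate_paired_conditions <- function(n_genes, shared_sd, private_sd,
                                       noise_sd, seed = 1L) {
  if (n_genes < 10L) stop("n_genes must be >= 10")
  if (any(c(shared_sd, private_sd, noise_sd) < 0))
    stop("SDs must be non-negative")
  if (shared_sd + private_sd + noise_sd == 0)
    stop("all SDs zero: degenerate generator")
  genes <- paste0("g", seq_len(n_genes))
  with_seed(seed, {
    s <- stats::rnorm(n_genes, 0, shared_sd)
    fc_a <- s + stats::rnorm(n_genes, 0, private_sd) +
      stats::rnorm(n_genes, 0, noise_sd)
    fc_b <- s + stats::rnorm(n_genes, 0, private_sd) +
      stats::rnorm(n_genes, 0, noise_sd)
    names(fc_a) <- names(fc_b) <- genes
    list(fc_a = fc_a, fc_b = fc_b,
         expected_r = shared_sd^2 /
           (shared_sd^2 + private_sd^2 + noise_sd^2))
  })
}

#' Shared/private SDs hitting a target expected correlation
#'
#' Splits unit total variance so that
#' `shared_sd^2 / (shared_sd^2 + private_sd^2 + noise_sd^2) = r`, with the
#' non-shared variance divided equally between the private and noise
#' components.
#'
#' @param r target expected Pearson correlation in `(0, 1)`.
#' @return list with `shared_sd`, `private_sd`, `noise_sd`.
#' @export
paired_sds_for_r <- function(r) {
  stopifnot(r > 0, r < 1)
  list(shared_sd = sqrt(r), private_sd = sqrt((1 - r) / 2),
       noise_sd = sqrt((1 - r) / 2))
}

#' Write a simulated study as a file bundle
#'
#' Emits the full plain-text bundle for one simulated dataset: expression
#' TSV, detection-p TSV, GMT, groups TSV, annotations TSV and a truth JSON
#' listing planted sets and affected genes.
#'
#' @param sim result of [simulate_dataset()].
#' @param sets the [gene_set_collection()] used.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_bundle <- function(sim, sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  write_expression_matrix(ds, file.path(dir, "expression.tsv"))
  write_expression_matrix(ds, file.path(dir, "detection.tsv"),
                          what = "detection_p")
  write_gmt(sets, file.path(dir, "sets.gmt"))
  utils::write.table(
    data.frame(sample = names(ds$groups), group = as.character(ds$groups)),
    file.path(dir, "groups.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(ds$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(planted_sets = sim$planted_sets,
         affected_genes = sim$affected_genes),
    file.path(dir, "truth.json"), auto_unbox = FALSE)
  invisible(dir)
}
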