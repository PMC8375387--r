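---
title: "Methods: rank-weighted gene-set scoring and cohort discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-weighted gene-set scoring and cohort discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `faimer`, the
parameters that matter, the numerical conventions, and the design choices
made where the design was genuinely open. It states no empirical result
that the package's tests and `scripts/acceptance.R` do not themselves
compute.

## The analysis in one paragraph

Candidate "mediated" gene sets are derived from a regulator-perturbation
contrast (e.g. knockdown vs. wild type): genes significantly
down-regulated under knockdown mark the processes the regulator sustains,
and the gene sets over-represented among them become candidates. Each
candidate is then scored *per sample* in independent case/control cohorts
by a rank-weighted single-sample method, giving a set × sample matrix.
Discrimination is quantified three ways: the overlap between the
candidate list and the sets up-regulated in patients (cumulative
hypergeometric tail), the ROC/AUC of a designated principal component of
the candidate-set score matrix, and a resampling null that asks whether
equally sized random set lists classify as well.

## Preprocessing

* **Detection filter.** A gene is kept if its detection p-value is below
  `alpha` (default 0.01, strict `<`) in *every* sample of at least one
  group — a gene silent in controls but reliably detected in patients
  survives. When no detection p-values exist the filter must be skipped
  explicitly; it is never skipped silently.
* **Annotation filters.** Multi-mapped rows are removed; genes on X/Y
  (matched case-insensitively against `X`, `Y`, `chrX`, `chrY`) are
  removed to avoid sex confounding in case/control contrasts; duplicate
  symbols are collapsed to the row with the highest mean expression.
  The collapse rule is a package convention (a common microarray
  practice), chosen because it keeps exactly one measurement per gene and
  is deterministic; each collapsed symbol is logged.
* **Order convention.** The pipeline applies the detection filter first.
  The two filters commute except in one corner: if the highest-mean row
  of a duplicated symbol is itself undetected, detection-first removes it
  while annotation-first would collapse onto it. Fixing the order makes
  the result well-defined; the tests assert commutativity on data without
  duplicate symbols and idempotence in general.

## Differential expression (SAM-style)

For gene *g* with group means `m1, m2` and within-group sums of squares,

```
d(g) = (m2 - m1) / (s(g) + s0),
s(g) = sqrt(((1/n1 + 1/n2) / (n1 + n2 - 2)) * (SS1 + SS2))
```

With `s0 = 0` this is the classical pooled-variance t statistic (the
tests assert equality to 1e-9). `s0 = "auto"` searches the percentiles of
`s` (steps of 5%) for the value minimizing the coefficient of variation
of `mad(d)` across `s`-quantile bins — the Tusher-style stabilization —
and logs the chosen value. The two-class unpaired, equal-variance pooled
form was chosen because it is the default two-class mode of SAM-style
analyses; the exchangeability constant mainly protects low-variance
genes from dominating the tails.

**Permutation FDR.** Group labels are permuted (`n_perm` Monte-Carlo
draws, or exhaustive enumeration of all distinct assignments when their
number is at most 10,000; a 3v3 design has exactly C(6,3) = 20). For each
gene,

```
q(g) = median_b #{|d_b| >= |d_obs(g)|} / #{|d_obs| >= |d_obs(g)|}
```

capped at 1 and made monotone non-increasing in |d| by
cumulative-minimum smoothing, so a q threshold always corresponds to a
|d| threshold. This median-count estimator was preferred over a
delta-table sweep because it is simpler, monotone by construction, and
directly testable against exhaustive enumeration. It is conservative when
many genes shift together (permutations then produce many large null
statistics simultaneously), which matters for heavily planted synthetic
data: with a 1-log2 shift in ~200 of 10,000 genes, only the few dozen
most extreme genes reach q < 0.01. Set-level derivation is robust to
this because Fisher enrichment needs only a modest deregulated list.

**Calls.** `up` iff `mean_diff > 0 ∧ 2^|mean_diff| > fc_threshold ∧
q < q_threshold` (both gates strict), `down` symmetric. Presets: `cells`
(FC > 1.3, q < 0.01) and `mouse` (FC > 1.3, q < 0.10). The condition
group (knockdown, patient, knockout) is always the second factor level,
named explicitly when groups are attached.

## Enrichment

One-sided Fisher exact test, computed as the hypergeometric upper tail
`P[X >= k]` with universe size `N`, set size within the universe `K`,
list size `n` and overlap `k`. Only enrichment is tested (depletion is
out of scope). The Benjamini–Hochberg `m` is the number of sets actually
tested after the minimum-overlap filter (default 3 genes in the
universe), so the correction universe is auditable from the result table.
The default enrichment universe is the genes surviving preprocessing —
the measured background — rather than all annotated genes; this is
configurable by passing any universe explicitly.

## Single-sample scoring

Within one sample, genes are ranked descending by expression (rank 1 =
highest; ties get average ranks, making the result order-independent) and
weighted

```
w(g) = x(g) * exp(-(r(g) - 1) / N)
```

A set's score is `mean(w[members]) - mean(w[non-members])`. The score is
column-local (sample `j`'s scores depend only on column `j`), higher
means the set is more highly expressed overall in that sample, and an
equal-size two-set partition satisfies `score(A) = -score(A^c)` exactly.
The exponential rank decay concentrates influence on highly expressed
genes; the weight scheme is pluggable (`weight_scheme = "rank_only"`
drops the expression factor) because the precise historical weighting of
rank-weighted single-sample scoring is not pinned down by its published
descriptions — all downstream guarantees are therefore asserted against
an independent brute-force implementation of the stated default, not
against external score values. Set-size bounds default to [5, 500]
measured genes; out-of-bounds sets are dropped with a warning.

One consequence worth knowing: because every set's score subtracts the
complement mean, a strong shift concentrated in one part of the genome
leaks a small opposite shift into *all* other sets' scores. The leakage
scales with the shifted fraction of the genome, which is why the
package's synthetic cohort studies use a whole-genome-scale 10,000-gene
universe (planted genes are then ~2% of the genome, as in real arrays)
rather than a toy genome.

## Set-level statistics

* **Group test.** Welch unequal-variance t per set, two-sided by default
  with a directional post-filter (`direction > 0 ∧ p < 0.05` defines the
  up-regulated list); a one-sided `greater` mode exists. Two-sided was
  chosen because the source analyses report "t-test: P < 0.05" plus a
  direction without stating sidedness. Zero-variance-in-both-groups sets
  are excluded as untestable, with a warning.
* **Overlap.** Cumulative hypergeometric tail over the universe of sets
  scored in both analyses — the smallest defensible universe; the
  universe size is printed in the result so it is auditable.
* **Clustering.** Rows are z-scored (expression heatmaps are
  row-relative; constant rows become zeros with a warning), then
  average-linkage agglomeration on Euclidean distances. Only the leaf
  order and merge structure are exposed; plotting is out of scope.
* **Concordance.** Pearson r on the shared-gene log2FC vectors with the
  two-sided t-transform p; `common_deregulated` intersects same-direction
  calls from the two differential tables.

## Classification

* **PCA.** Samples in set-score space. Default standardizes each set
  across samples first (sets have heterogeneous scales); raw-covariance
  mode by flag. Component signs are arbitrary in principle, so each
  component is deterministically oriented: condition-group mean
  coordinate ≥ control-group mean, ties resolved by making the
  largest-magnitude loading positive. Orientation makes AUC well-defined;
  under a true null it folds the AUC distribution upward (the oriented
  null AUC has median ≈ 0.55–0.59 at 10–15 samples per group, not 0.50),
  which the calibration tests account for.
* **AUC.** Mann–Whitney identity with average ranks — exactly equal to
  counting (control, condition) pairs with ties ½.
* **Designated component.** A configuration value, never a search over
  components (searching would bias AUC upward). The default is component
  2, matching the source study's discriminating axis for human cohorts;
  the synthetic planted-signal studies designate component 1, because a
  planted additive shift is the dominant variance direction in the
  generator, whereas in the real cohorts the dominant axis captured
  between-subject heterogeneity and the disease axis appeared second.
* **Resampling null.** `B` draws (default 1000) of `candidate_size` set
  names, uniform without replacement from the sets scored in every
  cohort; statistic = mean designated-component AUC across cohorts;
  `p_right = (1 + #{null >= observed}) / (B + 1)` (add-one, never zero).
  Because draws come from the full collection, they can include true
  candidate sets. At a 200-set universe with 10 strong candidates,
  ~8.6% of draws contain two or more of them, and such draws can tie a
  saturated observed AUC — a contamination floor of roughly 0.04–0.06 on
  `p_right` that no number of draws removes. With a realistically large
  set collection (thousands of terms) the floor is negligible. The
  calibration property is unaffected: when the candidate list itself is
  random, `p_right` is uniform.

## The synthetic-data generator

`expression(g, s) = baseline(g) + effect(g)·1[s ∈ condition] + ε`,
`ε ~ N(0, sd(g))`, with `baseline ~ U(4, 10)` log2 units and
`sd ~ U(0.2, 0.6)` — the intensity and noise ranges typical of summarized
expression arrays. `effect(g) = delta` for a `frac_affected_in_set` share
of each planted set's genes. Detection p-values follow a two-component
model — Beta(0.1, 10) for expressed genes, Uniform(0, 1) for a 5% silent
fraction — sufficient to exercise the detection filter without modeling
array background internals. Annotations plant duplicate symbols (2%,
with independent expression rows so the collapse is observable),
multi-mapped flags (2%) and X/Y labels (4%). Defaults emulate a small
two-group cohort (9 + 8 samples, 2,000 genes) of the kind used for
derivation contrasts; the cohort-validation studies in the tests and the
acceptance script use 10,000 genes and 10 + 10 samples (whole-genome
array scale after filtering, and the validation cohort sizes of the
motivating study).

What the generator does **not** emulate: probe-level effects, batch
effects, correlated (subject-level) biological noise, heavy-tailed
outlier samples, or RNA-seq count distributions. Passing tests therefore
demonstrate correctness and calibration of the *methods* under a clean
Gaussian additive model, not performance on real cohort data — real
between-subject correlation structure would lower AUCs and widen nulls.

The paired-condition generator produces two log2FC vectors
`fc = shared + private + noise` with independent Gaussian components;
its expected Pearson correlation is
`shared_sd² / (shared_sd² + private_sd² + noise_sd²)`, so a target
correlation (the cross-condition studies use 0.274) fixes the SDs in
closed form via `paired_sds_for_r()`, with the non-shared variance split
equally between private and noise components.

## Numerical conventions and degenerate inputs

* Missing values in expression input are hard errors with coordinates —
  summarized array matrices are complete, and silent imputation hides
  upstream problems. Linear-scale input is log2-transformed at read time
  (offset configurable); a zero with offset 0 is an error, not `-Inf`.
* Rank ties always use average ranks; AUC ties count ½; the add-one
  resampling estimator keeps p in (0, 1].
* Strict inequalities at every published-style gate (`FC > 1.3`,
  `q < 0.01`, `p < 0.05`, detection `p < 0.01`).
* Exhaustive permutation is refused above 10,000 assignments; Monte-Carlo
  permutation warns below 50 draws.
* Every generator and every stochastic stage takes an explicit seed and
  restores the caller's RNG state; pipeline results carry the seed in a
  provenance record, and identical config + seed reproduces result tables
  byte for byte.

## Problem sizes used by the test suite

Oracle-equivalence tests run at small, exactly checkable sizes (e.g.
200 genes × 12 samples × 15 sets for scoring; all hypergeometric grids to
N = 20; 500 AUC fixtures to n = 50; exhaustive 3v3 permutation
enumeration). Calibration studies use 2,000-gene null datasets (20
seeds), 200-set score matrices, and 200 outer resampling replicates at
B = 99 with 15 + 15 samples — the sample size chosen so the discrete AUC
grid (225 distinguishable pair fractions) does not create tie artifacts
in the uniformity check. Recovery studies use the 10,000-gene,
200-set, 10-candidate design with 50 seeded replicates at B = 1000.

## Known limitations

* The permutation FDR is conservative under strong widespread signal
  (no π₀ correction); derivation compensates at the enrichment stage.
* The resampling null inherits the contamination floor described above
  whenever the candidate list is a non-negligible fraction of the set
  collection.
* Gene sets are flat member lists; no set-hierarchy (DAG) semantics, no
  competing single-sample kernels, no supervised classifiers — these are
  deliberate non-goals of the package.
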