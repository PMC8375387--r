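two_group_ds <- function(x1, x2, gene = "g1") {
  vals <- matrix(c(x1, x2), nrow = 1,
                 dimnames = list(gene, paste0("s", seq_along(c(x1, x2)))))
  g <- setNames(c(rep("control", length(x1)),
                  rep("condition", length(x2))), colnames(vals))
  set_groups(expression_dataset(vals), g, condition = "condition")
}

test_that("SAM d matches the hand-evaluated pooled formula", {
  ds <- two_group_ds(c(1, 2, 3), c(4, 5, 6))
  st <- sam_statistics(ds, s0 = 0)
  expect_equal(st$s, sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(st$d, 3.674235, tolerance = 1e-5)
  same <- two_group_ds(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sam_statistics(same, s0 = 0)$d, 0)
})

test_that("|d| is non-increasing in s0", {
  ds <- random_dataset(n_genes = 100L, n1 = 4L, n2 = 4L, seed = 2L)
  d0 <- abs(sam_statistics(ds, s0 = 0)$d)
  d1 <- abs(sam_statistics(ds, s0 = 0.5)$d)
  d2 <- abs(sam_statistics(ds, s0 = 2)$d)
  expect_true(all(d1 <= d0 + 1e-12))
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("with s0 = 0, d equals the classical pooled-variance t statistic", {
  for (seed in 1:5) {
    ds <- random_dataset(n_genes = 40L, n1 = 4L, n2 = 6L, seed = seed)
    st <- sam_statistics(ds, s0 = 0)
    idx <- faimer:::group_indices(ds)
    ref <- vapply(seq_len(40L), function(i)
      pooled_t_oracle(ds$values[i, idx$control],
                      ds$values[i, idx$condition]), 0)
    expect_lt(max(abs(st$d - ref)), 1e-9)
  }
})

test_that("label swap negates d and mean_diff, leaves fc and q unchanged", {
  ds <- random_dataset(n_genes = 60L, n1 = 3L, n2 = 3L, seed = 3L)
  swapped <- ds
  swapped$groups <- factor(ds$groups, levels = rev(levels(ds$groups)))
  a <- sam_statistics(ds, s0 = 0.1)
  b <- sam_statistics(swapped, s0 = 0.1)
  expect_equal(b$d, -a$d, tolerance = 1e-12)
  expect_equal(fold_change(swapped)$mean_diff, -fold_change(ds)$mean_diff)
  expect_equal(fold_change(swapped)$fc, fold_change(ds)$fc)
  qa <- suppressMessages(estimate_fdr_permutation(ds, a$d, 0.1,
                                                  n_perm = "exhaustive"))
  qb <- suppressMessages(estimate_fdr_permutation(swapped, b$d, 0.1,
                                                  n_perm = "exhaustive"))
  expect_equal(as.numeric(qa), as.numeric(qb), tolerance = 1e-12)
})

test_that("exhaustive 3v3 enumeration uses exactly C(6,3) = 20 assignments", {
  ds <- random_dataset(n_genes = 30L, n1 = 3L, n2 = 3L, seed = 4L)
  st <- sam_statistics(ds, s0 = 0.2)
  q <- suppressMessages(
    estimate_fdr_permutation(ds, st$d, 0.2, n_perm = "exhaustive"))
  expect_identical(attr(q, "n_perm_used"), 20L)
  expect_true(all(q >= 0 & q <= 1))
  # q monotone non-increasing in |d|
  ord <- order(-abs(st$d))
  expect_true(all(diff(q[ord]) >= -1e-12))
})

test_that("exhaustive q matches Monte-Carlo q within Monte-Carlo error", {
  ds <- random_dataset(n_genes = 80L, n1 = 3L, n2 = 3L, seed = 5L)
  st <- sam_statistics(ds, s0 = 0.2)
  qe <- suppressMessages(
    estimate_fdr_permutation(ds, st$d, 0.2, n_perm = "exhaustive"))
  qm <- estimate_fdr_permutation(ds, st$d, 0.2, n_perm = 5000L, seed = 1L)
  # the per-permutation count distribution has 20 atoms, so the sampled
  # median can land one atom away from the exhaustive one; agreement is
  # within that discreteness plus Monte-Carlo noise
  expect_lt(max(abs(qe - qm)), 0.1)
  expect_lt(mean(abs(qe - qm)), 0.02)
})

test_that("a strongly shifted gene attains the minimum q", {
  set.seed(10)
  n1 <- 10L; n2 <- 10L
  vals <- matrix(rnorm(501 * 20, 6, 0.5), 501, 20,
                 dimnames = list(paste0("g", 1:501), paste0("s", 1:20)))
  vals["g1", 11:20] <- vals["g1", 11:20] + 4
  g <- setNames(c(rep("control", 10), rep("condition", 10)),
                colnames(vals))
  ds <- set_groups(expression_dataset(vals), g, condition = "condition")
  st <- sam_statistics(ds, s0 = 0)
  q <- estimate_fdr_permutation(ds, st$d, 0, n_perm = 100L, seed = 2L)
  expect_equal(which.min(q), 1L)
  expect_lte(q[1], min(q[-1]))
})

test_that("fold changes carry magnitude and direction", {
  fcs <- fold_change(two_group_ds(c(4, 4), c(5, 5)))
  expect_equal(fcs$fc, 2); expect_gt(fcs$mean_diff, 0)
  expect_equal(fold_change(two_group_ds(c(4, 4), c(4, 4)))$fc, 1)
  down <- fold_change(two_group_ds(c(5, 5), c(4.62, 4.62)))
  expect_equal(down$fc, 2^0.38, tolerance = 1e-6)
  expect_gt(down$fc, 1.3)
  expect_lt(down$mean_diff, 0)
})

test_that("deregulation calls apply strict FC and FDR gates", {
  tab <- data.frame(gene = c("a", "b", "c"),
                    d = c(3, 2, -4), mean_diff = c(0.585, 0.263, -0.515),
                    fc = c(1.5, 1.2, 1 / 0.7), q = c(0.005, 0.001, 0.004))
  out <- call_deregulated(tab, 1.3, 0.01)
  expect_identical(out$call, c("up", "none", "down"))
  expect_identical(attr(out, "up_genes"), "a")
  expect_identical(attr(out, "down_genes"), "c")
  expect_error(call_deregulated(tab, 0.9, 0.01), "fc_threshold")
  expect_error(call_deregulated(tab, 1.3, 1.5), "q_threshold")
})

test_that("null datasets rarely reach q < 0.1", {
  fracs <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_genes = 2000L,
                             n_samples_per_group = c(5L, 5L),
                             delta = 0, seed = 100L + s)
    ds <- simulate_dataset(cfg)$dataset
    st <- sam_statistics(ds, s0 = 0)
    q <- estimate_fdr_permutation(ds, st$d, 0, n_perm = 60L,
                                  seed = s)
    mean(q < 0.1)
  }, 0)
  expect_lte(mean(fracs), 0.15)
})
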