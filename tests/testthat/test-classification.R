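make_ssm <- function(scores, groups = NULL, condition = "condition") {
  g <- NULL
  if (!is.null(groups)) {
    g <- factor(groups, levels = c(setdiff(unique(groups), condition),
                                   condition))
    names(g) <- colnames(scores)
  }
  structure(list(scores = scores, groups = g), class = "set_score_matrix")
}

test_that("PCA recovers closed-form explained variance of a 2x2 covariance", {
  # three zero-mean samples whose sample covariance is [[2,1],[1,2]]
  pts <- sqrt(2) * rbind(c(1, 0), c(0, 1), c(-1, -1))
  expect_equal(cov(pts), matrix(c(2, 1, 1, 2), 2), tolerance = 1e-12)
  ssm <- make_ssm(t(pts), groups = NULL)
  dimnames(ssm$scores) <- list(c("m1", "m2"), c("s1", "s2", "s3"))
  pc <- pca_transform(ssm, standardize = FALSE)
  expect_equal(pc$explained_variance, c(0.75, 0.25), tolerance = 1e-9)
})

test_that("collinear samples load entirely on the first component", {
  base <- seq(-2, 2, length.out = 5)
  sc <- rbind(m1 = 3 * base + 1, m2 = -2 * base + 4)
  colnames(sc) <- paste0("s", 1:5)
  pc <- pca_transform(make_ssm(sc), standardize = FALSE)
  expect_equal(pc$explained_variance[1], 1, tolerance = 1e-9)
})

test_that("rotation is orthonormal and reconstruction is exact", {
  set.seed(5)
  sc <- matrix(rnorm(6 * 9), 6, 9,
               dimnames = list(paste0("m", 1:6), paste0("s", 1:9)))
  pc <- pca_transform(make_ssm(sc), standardize = FALSE)
  rt <- crossprod(pc$rotation)
  expect_lt(max(abs(rt - diag(ncol(rt)))), 1e-9)
  recon <- pc$coordinates %*% t(pc$rotation)
  centered <- t(sc) - matrix(rowMeans(sc), 9, 6, byrow = TRUE)
  expect_lt(max(abs(recon - centered)), 1e-9)
})

test_that("component orientation puts the condition group on the high side", {
  set.seed(6)
  sc <- matrix(rnorm(4 * 12), 4, 12,
               dimnames = list(paste0("m", 1:4), paste0("s", 1:12)))
  grp <- rep(c("control", "condition"), each = 6)
  sc[, grp == "condition"] <- sc[, grp == "condition"] + 2
  pc <- pca_transform(make_ssm(sc, grp))
  v <- pc$coordinates[, 1]
  expect_gte(mean(v[grp == "condition"]) - mean(v[grp == "control"]), 0)
})

test_that("PC separation test behaves like a Welch t test on coordinates", {
  set.seed(7)
  sc <- matrix(rnorm(3 * 17), 3, 17,
               dimnames = list(paste0("m", 1:3), paste0("s", 1:17)))
  grp <- c(rep("control", 9), rep("condition", 8))
  sc[1, grp == "condition"] <- sc[1, grp == "condition"] + 5
  pc <- pca_transform(make_ssm(sc, grp), standardize = FALSE)
  res <- pc_separation_test(pc, component = 1L)
  expect_lt(res$p, 1e-4)
  ref <- t.test(pc$coordinates[grp == "condition", 1],
                pc$coordinates[grp == "control", 1])
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-9)
  expect_error(pc_separation_test(pc, component = 99L), "not available")
})

test_that("AUC equals exhaustive pair counting with tie halving", {
  expect_equal(roc_auc(c(1, 2, 3, 4),
                       c("ctl", "ctl", "pah", "pah"), "pah")$auc, 1)
  expect_equal(roc_auc(rep(2, 6), rep(c("ctl", "pah"), 3), "pah")$auc, 0.5)
  expect_equal(roc_auc(c(1, 3, 2, 4),
                       c("ctl", "ctl", "pah", "pah"), "pah")$auc, 0.75)
  set.seed(8)
  for (rep in 1:50) {
    n <- sample(4:50, 1)
    labels <- sample(c("ctl", "pah"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    values <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # forces ties
    expect_equal(roc_auc(values, labels, "pah")$auc,
                 auc_oracle(values, labels, "pah"), tolerance = 1e-12)
  }
})

test_that("AUC flips to its complement under label swap", {
  set.seed(9)
  values <- rnorm(20)
  labels <- rep(c("a", "b"), 10)
  expect_equal(roc_auc(values, labels, "b")$auc,
               1 - roc_auc(values, labels, "a")$auc, tolerance = 1e-12)
})

test_that("ROC points trace a valid curve from (0,0) to (1,1)", {
  res <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c("n", "n", "p", "p"), "p")
  expect_equal(res$roc$fpr[1], 0)
  expect_equal(res$roc$tpr[1], 0)
  expect_equal(res$roc$fpr[nrow(res$roc)], 1)
  expect_equal(res$roc$tpr[nrow(res$roc)], 1)
  expect_true(all(diff(res$roc$fpr) >= 0) && all(diff(res$roc$tpr) >= 0))
})

test_that("resampling null is seeded, add-one estimated, and self-consistent", {
  set.seed(10)
  sc <- matrix(rnorm(30 * 12), 30, 12,
               dimnames = list(sprintf("set%02d", 1:30), paste0("s", 1:12)))
  grp <- rep(c("control", "condition"), each = 6)
  cand <- sprintf("set%02d", 1:5)
  sc[cand, grp == "condition"] <- sc[cand, grp == "condition"] + 4
  ssm <- make_ssm(sc, grp)
  r1 <- resample_random_sets(ssm, cand, component = 1L, B = 50L, seed = 3L)
  r2 <- resample_random_sets(ssm, cand, component = 1L, B = 50L, seed = 3L)
  expect_identical(r1$null_aucs, r2$null_aucs)
  expect_equal(r1$p_right,
               (1 + sum(r1$null_aucs >= r1$observed)) / (r1$B + 1))
  expect_gt(r1$observed, 0.9)
  expect_lte(r1$p_right, 1)
  expect_error(resample_random_sets(ssm, cand, B = 0L), "B must be")
  expect_error(resample_random_sets(ssm, sprintf("set%02d", 1:40)),
               "not scored|exceeds")
})
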