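score_matrix <- function(scores, groups, condition = "condition") {
  g <- factor(groups, levels = c(setdiff(unique(groups), condition),
                                 condition))
  names(g) <- colnames(scores)
  structure(list(scores = scores, groups = g), class = "set_score_matrix")
}

test_that("set-level group test matches Welch t.test and flags direction", {
  set.seed(1)
  sc <- matrix(rnorm(5 * 17), 5, 17,
               dimnames = list(paste0("m", 1:5), paste0("s", 1:17)))
  grp <- c(rep("control", 9), rep("condition", 8))
  sc[1, grp == "condition"] <- sc[1, grp == "condition"] + 10
  ssm <- score_matrix(sc, grp)
  res <- set_group_test(ssm)
  for (i in 1:5) {
    tt <- t.test(sc[i, grp == "condition"], sc[i, grp == "control"])
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-9)
  }
  expect_lt(res$p[1], 1e-6)
  expect_identical(res$direction[1], 1)
  expect_true("m1" %in% attr(res, "up_sets"))
})

test_that("identical group score distributions give t = 0 and no up call", {
  sc <- matrix(rep(c(1, 2, 3, 1, 2, 3), each = 2), 2, 6,
               dimnames = list(c("m1", "m2"), paste0("s", 1:6)))
  ssm <- score_matrix(sc, rep(c("control", "condition"), each = 3))
  res <- set_group_test(ssm)
  expect_equal(res$t, c(0, 0))
  expect_length(attr(res, "up_sets"), 0L)
})

test_that("swapping group labels negates t and keeps the two-sided p", {
  set.seed(2)
  sc <- matrix(rnorm(4 * 10), 4, 10,
               dimnames = list(paste0("m", 1:4), paste0("s", 1:10)))
  a <- set_group_test(score_matrix(sc, rep(c("control", "condition"),
                                           each = 5)))
  b <- set_group_test(score_matrix(sc, rep(c("control", "condition"),
                                           each = 5),
                                   condition = "control"))
  expect_equal(b$t, -a$t, tolerance = 1e-12)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("untestable zero-variance sets are excluded with a warning", {
  sc <- rbind(m1 = rep(1, 6), m2 = c(1, 2, 3, 4, 5, 6))
  colnames(sc) <- paste0("s", 1:6)
  ssm <- score_matrix(sc, rep(c("control", "condition"), each = 3))
  expect_warning(res <- set_group_test(ssm), "untestable")
  expect_identical(res$set, "m2")
})

test_that("overlap tail probabilities match enumeration and direct summation", {
  universe <- paste0("t", 1:10)
  ov <- overlap_hypergeometric(universe[1:5], universe[c(1:4)], universe)
  expect_equal(ov$p, 5 / 210, tolerance = 1e-12)
  expect_identical(ov$overlap, 4L)
  disjoint <- overlap_hypergeometric(universe[1:3], universe[8:10], universe)
  expect_equal(disjoint$p, 1)
  set.seed(3)
  for (rep in 1:20) {
    N <- sample(4:12, 1)
    uni <- paste0("t", 1:N)
    A <- sample(uni, sample(1:N, 1))
    B <- sample(uni, sample(1:N, 1))
    ov <- overlap_hypergeometric(A, B, uni)
    expect_equal(ov$p,
                 hyper_tail_oracle(ov$overlap, length(A), N, length(B)),
                 tolerance = 1e-12)
  }
  expect_error(overlap_hypergeometric(c("t1", "qq"), "t1", universe), "qq")
})

test_that("cluster order merges identical columns first and is structure-stable", {
  set.seed(4)
  m <- matrix(rnorm(8 * 5), 8, 5,
              dimnames = list(paste0("r", 1:8), paste0("c", 1:5)))
  m[, 5] <- m[, 4]
  ord <- cluster_order(m, axis = "columns")
  hc <- attr(ord, "hclust")
  expect_equal(hc$height[1], 0)               # identical columns merge first
  expect_setequal(abs(hc$merge[1, ]), c(4, 5))
  # 1-D points {0, 1, 10} as columns: {0,1} merge before 10 joins
  m1 <- matrix(c(0, 1, 10, 0, 1, 10), 2, 3, byrow = TRUE,
               dimnames = list(c("r1", "r2"), c("a", "b", "c")))
  hc1 <- attr(cluster_order(m1, axis = "columns"), "hclust")
  expect_setequal(abs(hc1$merge[1, ]), c(1, 2))
  # permuting input rows preserves the merge-height structure
  perm <- c(3, 1, 5, 2, 8, 7, 6, 4)
  hp <- attr(cluster_order(m[perm, ], axis = "rows"), "hclust")
  ho <- attr(cluster_order(m, axis = "rows"), "hclust")
  expect_equal(sort(hp$height), sort(ho$height), tolerance = 1e-12)
})

test_that("constant rows are z-scored to zeros with a warning", {
  m <- rbind(r1 = rep(2, 4), r2 = c(1, 2, 3, 4), r3 = c(4, 3, 2, 1))
  colnames(m) <- paste0("c", 1:4)
  expect_warning(cluster_order(m, axis = "rows"), "constant")
})

test_that("log2FC concordance reproduces hand-computed correlations", {
  fc <- setNames(rnorm(10), paste0("g", 1:10))
  expect_equal(logfc_concordance(fc, fc)$r, 1)
  expect_equal(logfc_concordance(fc, -fc)$r, -1)
  x <- setNames(c(1, 2, 3), c("a", "b", "c"))
  y <- setNames(c(2, 1, 3), c("a", "b", "c"))
  expect_equal(logfc_concordance(x, y)$r, 0.5, tolerance = 1e-12)
  expect_error(logfc_concordance(x[1:2], y[1:2]), ">= 3")
  expect_error(logfc_concordance(setNames(rep(1, 3), names(x)), y),
               "zero variance")
})

test_that("common deregulated genes require matching direction calls", {
  fc_a <- setNames(c(1, -1, 2, 0.1), paste0("g", 1:4))
  fc_b <- setNames(c(1.2, -0.9, -2, 0.2), paste0("g", 1:4))
  calls_a <- setNames(c("up", "down", "up", "none"), names(fc_a))
  calls_b <- setNames(c("up", "down", "down", "none"), names(fc_b))
  res <- logfc_concordance(fc_a, fc_b, calls_a, calls_b)
  expect_setequal(res$common_deregulated, c("g1", "g2"))
})
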