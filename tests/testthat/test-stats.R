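test_that("observed chi-squared matches the textbook Pearson formula", {
  grade <- rep(c("g1", "g2"), c(30, 35))
  cat_ <- c(rep(c("a", "b"), c(10, 20)), rep(c("a", "b"), c(25, 10)))
  res <- permutationChisq(grade, cat_, nPerm = 200, seed = 1)
  tab <- table(grade, cat_)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - expected)^2 / expected)
  expect_equal(res$statistic, hand, tolerance = 1e-12)
})

test_that("maximal association reaches the smallest attainable p", {
  grade <- rep(c("g1", "g2"), each = 50)
  cat_ <- rep(c("a", "b"), each = 50)
  res <- permutationChisq(grade, cat_, nPerm = 999, seed = 2)
  expect_equal(res$p.value, 1 / 1000)
})

test_that("permutation tests are seeded-reproducible and bounded", {
  g <- rep(1:2, each = 40); ct <- sample(c("a", "b"), 80, TRUE)
  r1 <- permutationChisq(g, ct, nPerm = 300, seed = 7)
  r2 <- permutationChisq(g, ct, nPerm = 300, seed = 7)
  expect_identical(r1$p.value, r2$p.value)
  expect_gte(r1$p.value, 1 / 301)
  expect_lte(r1$p.value, 1)

  a <- rnorm(30); b <- rnorm(30)
  d1 <- permutationDiffTest(a, b, nPerm = 300, seed = 7)
  d2 <- permutationDiffTest(a, b, nPerm = 300, seed = 7)
  expect_identical(d1$p.value, d2$p.value)
  expect_gte(d1$p.value, 1 / 301)
  ## the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(permutationDiffTest(a, b, nPerm = 50, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("grades with no cells are dropped with a warning", {
  g <- factor(rep(c("g1", "g2"), each = 30), levels = c("g1", "g2", "g3"))
  ct <- sample(c("a", "b"), 60, TRUE)
  expect_warning(res <- permutationChisq(g, ct, nPerm = 99, seed = 1), "g3")
  expect_equal(nrow(res$table), 2L)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  q <- bhAdjust(p)
  m <- length(p)
  hand <- rev(cummin(rev(m * p / seq_len(m))))   # p already sorted
  expect_equal(q, pmin(hand, 1))
  expect_true(all(q >= p))
  ## order invariance
  idx <- sample(m)
  expect_equal(bhAdjust(p[idx]), q[idx])
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("median-difference permutation test behaves at the extremes", {
  set.seed(4)
  x <- rnorm(50)
  r <- permutationDiffTest(x, x, nPerm = 200, seed = 5)
  expect_equal(r$statistic, 0)
  expect_gt(r$p.value, 0.99)

  set.seed(6)
  a <- rnorm(200); b <- rnorm(200, 5)
  r2 <- permutationDiffTest(a, b, nPerm = 499, seed = 6)
  expect_equal(r2$p.value, 1 / 500)
  expect_error(permutationDiffTest(numeric(0), b), "non-empty")
})

test_that("Kruskal-Wallis matches the hand-computed rank statistic", {
  ## groups (1,2,3), (4,5,6), (7,8,9): ranks are the values, no ties;
  ## H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 = 7.2
  res <- kruskalWallis(1:9, rep(1:3, each = 3))
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_equal(res$df, 2L)
  expect_equal(res$p.value, pchisq(7.2, 2, lower.tail = FALSE))

  same <- kruskalWallis(rep(2, 10), rep(1:2, each = 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(kruskalWallis(1:5, rep(1, 5)), "2 non-empty")
})

test_that("fold changes are ratios of medians on the linear scale", {
  expect_equal(logFoldChange(c(2, 8, 14), c(2, 8, 14))$fold, 1)
  r <- logFoldChange(c(6, 8, 10), c(1, 2, 3))
  expect_equal(r$fold, 4)
  expect_equal(r$log2_fold, 2)
  expect_true(is.na(logFoldChange(c(-3, 1), c(1, 2))$fold))
})

test_that("median dichotomization uses the >= far convention", {
  s <- dichotomizeByMedian(c(1, 2, 3, 4))
  expect_equal(s$cutoff, 2.5)
  expect_equal(as.character(s$group), c("near", "near", "far", "far"))
  ## a value exactly at the cutoff goes far
  s2 <- dichotomizeByMedian(c(10, 20, 30))
  expect_equal(as.character(s2$group)[2], "far")
  s3 <- dichotomizeByMedian(c(1, NA, 3, 5))
  expect_true(is.na(as.character(s3$group)[2]))
  expect_equal(as.character(s3$group)[3], "far")
  expect_error(dichotomizeByMedian(c(NA, NA, 1)), "at least 2")
})

test_that("log-rank matches a hand-tabulated two-group computation", {
  ## all events, group A at t=1,2,3 and group B at t=4,5,6
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(TRUE, 6)
  group <- factor(rep(c("A", "B"), each = 3))
  ## hand tabulation of observed minus expected for group A and variance
  oe <- 0; v <- 0
  for (t in time) {
    at_risk <- time >= t
    n <- sum(at_risk); nA <- sum(at_risk & group == "A")
    d <- sum(time == t)
    oe <- oe + (sum(time == t & group == "A") - d * nA / n)
    if (n > 1) v <- v + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  hand <- oe^2 / v
  res <- kmLogrank(time, event, group)
  expect_equal(res$statistic, hand, tolerance = 1e-10)
  ## swapping group labels leaves the statistic unchanged
  swapped <- kmLogrank(time, event, factor(group,
                                           levels = rev(levels(group))))
  expect_equal(swapped$statistic, res$statistic, tolerance = 1e-12)
})

test_that("log-rank degenerates to zero for identical groups", {
  time <- rep(c(2, 5, 9), 2)
  event <- rep(TRUE, 6)
  group <- factor(rep(c("A", "B"), each = 3))
  res <- kmLogrank(time, event, group)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p.value, 1)
})

test_that("KM estimates equal empirical survival without censoring", {
  time <- c(1, 3, 4, 7, 9, 2, 5, 6, 8, 10)
  event <- rep(TRUE, 10)
  group <- factor(rep(c("A", "B"), each = 5))
  res <- kmLogrank(time, event, group)
  sA <- res$fit$surv[seq_len(res$fit$strata[1])]
  tA <- res$fit$time[seq_len(res$fit$strata[1])]
  emp <- vapply(tA, function(t) mean(time[group == "A"] > t), numeric(1))
  expect_equal(sA, emp, tolerance = 1e-12)
  expect_true(all(diff(res$fit$surv[seq_len(res$fit$strata[1])]) <= 0))
})

test_that("administrative censoring re-censors long follow-up", {
  time <- c(10, 80, 30, 90)
  event <- c(TRUE, TRUE, TRUE, TRUE)
  group <- factor(c("A", "A", "B", "B"))
  res <- kmLogrank(time, event, group, censorAt = 60)
  expect_equal(sum(res$fit$n.event), 2)
  expect_error(kmLogrank(c(5, 6), c(FALSE, FALSE), factor(c("A", "B"))),
               "event")
  expect_error(kmLogrank(c(5, 6), c(TRUE, TRUE), factor(c("A", "A"))),
               "two non-empty")
})
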