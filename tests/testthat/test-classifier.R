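test_that("EM recovers two-component mixture parameters", {
  set.seed(101)
  n <- 5000
  z <- runif(n) < 0.3
  x <- ifelse(z, rnorm(n, 6, 1), rnorm(n, 2, 1))
  fit <- fitGmmEM(x, emConfig(K = 2))
  expect_true(fit@converged)
  ord <- order(fit@means)
  expect_lt(max(abs(fit@means[ord] - c(2, 6))), 0.1)
  expect_lt(max(abs(fit@weights[ord] - c(0.7, 0.3))), 0.03)
  expect_lt(max(abs(sqrt(fit@variances[ord]) - c(1, 1))), 0.1)
  ## log-likelihood non-decreasing at every iteration
  expect_true(all(diff(fit@logLik) >= -1e-8 * (1 + abs(fit@logLik[-1]))))
})

test_that("EM is a fixed point at convergence", {
  set.seed(102)
  x <- c(rnorm(2000, 0, 1), rnorm(1000, 5, 1))
  cfg <- emConfig(K = 2)
  fit <- fitGmmEM(x, cfg)
  ## one extra manual EM step barely moves the parameters
  g <- posteriorProbs(x, fit)
  nk <- colSums(g)
  w1 <- nk / length(x)
  m1 <- colSums(g * x) / nk
  v1 <- colSums(g * (outer(x, m1, "-")^2)) / nk
  rel <- function(a, b) abs(a - b) / (1 + abs(b))
  expect_lt(max(rel(w1, fit@weights)), 10 * cfg$eps * 1e4)
  expect_lt(max(rel(m1, fit@means)), 1e-3)
  expect_lt(max(rel(v1, fit@variances)), 1e-3)
})

test_that("degenerate inputs are rejected and K = 1 is the Gaussian MLE", {
  expect_error(fitGmmEM(rep(1, 100), emConfig(K = 2)), "distinct")
  expect_error(fitGmmEM(c(1, 2, 3), emConfig(K = 2)), "distinct")
  x <- c(1.5, 2.5, 3.5, 9)
  fit <- fitGmmEM(x, emConfig(K = 1))
  expect_equal(fit@means, mean(x))
  expect_equal(fit@variances, mean((x - mean(x))^2))
  expect_equal(fit@weights, 1)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(103)
  x <- c(rnorm(1500, 1, 0.8), rnorm(800, 5, 1.2))
  fit <- fitGmmEM(x, emConfig(K = 2))
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(max(abs(sort(fit@means) - sort(as.numeric(mc$parameters$mean)))),
            0.05)
  expect_lt(max(abs(sort(fit@weights) - sort(mc$parameters$pro))), 0.02)
})

test_that("posterior rows sum to one", {
  set.seed(104)
  x <- c(rnorm(500), rnorm(500, 4))
  fit <- fitGmmEM(x, emConfig(K = 2))
  g <- posteriorProbs(x, fit)
  expect_lt(max(abs(rowSums(g) - 1)), 1e-10)
})

test_that("positivity calls follow the highest-mean component posterior", {
  fit <- new("MixtureFit", K = 2L, weights = c(0.5, 0.5), means = c(0, 10),
             variances = c(1, 1), logLik = -1, nIter = 1L,
             converged = TRUE, n = 100L)
  expect_true(classifyPositive(10, fit))
  expect_false(classifyPositive(0, fit))
  ## exact posterior tie at the symmetric midpoint breaks negative
  expect_false(classifyPositive(5, fit))

  ## brute-force posterior oracle on a random sample and random parameters
  set.seed(105)
  fit2 <- new("MixtureFit", K = 3L, weights = c(0.5, 0.3, 0.2),
              means = c(-1, 2, 6), variances = c(0.5, 2, 1),
              logLik = -1, nIter = 1L, converged = TRUE, n = 100L)
  x <- runif(300, -4, 9)
  dens <- sapply(1:3, function(k) fit2@weights[k] *
                   dnorm(x, fit2@means[k], sqrt(fit2@variances[k])))
  expected <- apply(dens, 1, which.max) == 3L
  expect_identical(classifyPositive(x, fit2), expected)
})

test_that("marker combination is a logical OR", {
  expect_true(combineMarkersOr(cbind(p63 = TRUE, CK5 = FALSE)))
  expect_false(combineMarkersOr(cbind(p63 = FALSE, CK5 = FALSE)))
  ## exhaustive truth tables for 2 and 4 markers
  for (m in c(2L, 4L)) {
    grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
    expect_identical(combineMarkersOr(grid), rowSums(grid) > 0)
  }
  expect_error(combineMarkersOr(matrix(c(0, 2), 1)), "logical or 0/1")
})

test_that("CE/N-CE labels follow basal positivity and compartment", {
  df <- rbind(makeCellDF(1, cell_id = "epi_neg"),
              makeCellDF(1, cell_id = "epi_pos"),
              makeCellDF(1, cell_id = "stro", compartment = "stromal",
                         cell_area = 400))
  tab <- makeTable(df)
  out <- labelCeNce(tab, c(FALSE, TRUE, TRUE))
  expect_equal(cellData(out)$cell_type, c("CE", "N-CE", "stroma"))
})

test_that("calls at 4-sd separation match the generating component", {
  set.seed(106)
  n <- 4000
  z <- runif(n) < 0.3
  x <- ifelse(z, rnorm(n, 4, 1), rnorm(n, 0, 1))
  fit <- fitGmmEM(x, emConfig(K = 2))
  calls <- classifyPositive(x, fit)
  expect_gt(mean(calls == z), 0.97)
})

test_that("cell classification on a synthetic core beats 95% accuracy", {
  core <- simulateCore(smallCoreConfig(seed = 21L))
  tab <- normalizeLog2(applyQC(core$table)$table)
  cls <- suppressWarnings(classifyCells(tab))
  conf <- epithelialConfusion(cls$table, core$truth)
  expect_gt(conf$acc, 0.95)
})

test_that("immune phenotypes follow the composition rules", {
  calls <- data.frame(
    CD3   = c(TRUE,  TRUE,  FALSE, FALSE, TRUE),
    CD4   = c(TRUE,  TRUE,  FALSE, FALSE, FALSE),
    CD8   = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    CD68  = c(FALSE, FALSE, TRUE,  FALSE, FALSE),
    FOXP3 = c(TRUE,  FALSE, FALSE, FALSE, FALSE))
  expect_equal(assignImmunePhenotypes(calls),
               c("T_reg", "T_H", "macrophage", "other", "other"))
  ## overlapping convention: T_reg cells also satisfy the T_H rule, and the
  ## more specific T_reg label wins
  expect_equal(assignImmunePhenotypes(calls, thIncludesTreg = TRUE)[1],
               "T_reg")
  expect_error(assignImmunePhenotypes(calls[, -5]), "FOXP3")
})
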