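test_that("cells pick up the mask label under their pixel", {
  m <- matrix(0L, 10, 10); m[3:5, 3:5] <- 2L
  mask <- GlandMask(m)
  df <- makeCellDF(3, cell_id = c("in", "out", "oob"))
  df$x <- c(3, 8, 50); df$y <- c(3, 8, 2)
  tab <- makeTable(df)
  expect_warning(out <- assignCellsToGlands(tab, mask), "outside")
  expect_equal(cellData(out)$gland_id, c(2L, 0L, 0L))
})

test_that("the gland eligibility ratio is area per N-CE cell", {
  gl <- data.frame(gland_id = 1:3, area_px = c(100000L, 100000L, 5000L),
                   centroid_x = 0, centroid_y = 0, n_cells = c(5L, 20L, 10L),
                   n_epithelial = c(5L, 20L, 10L), n_nce = c(2L, 10L, 0L))
  out <- filterGlandsByRatio(gl, threshold = 25000)
  expect_equal(out$eligible, c(FALSE, TRUE, FALSE))
  expect_equal(out$ratio[1:2], c(50000, 10000))
  expect_equal(out$ratio[3], Inf)
})

test_that("MST ordering recovers paths and respects tree minimality", {
  ## collinear points in shuffled order come out in coordinate order
  pts <- cbind(c(3, 0, 2, 1), 0)
  ord <- mstOrder(pts)
  expect_true(identical(pts[ord, 1], c(0, 1, 2, 3)) ||
              identical(pts[ord, 1], c(3, 2, 1, 0)))
  expect_setequal(ord, 1:4)

  expect_setequal(mstOrder(cbind(c(0, 1), c(0, 0))), 1:2)
  expect_error(mstOrder(cbind(1, 1)), "at least 2")

  ## the spanning tree the ordering is built on is the exhaustive minimum
  set.seed(31)
  for (i in 1:10) {
    p <- matrix(runif(10), 5, 2)
    d <- as.matrix(dist(p))
    tree <- glandmark:::.buildMST(d)
    expect_equal(sum(igraph::E(tree)$weight), bruteMSTWeight(d),
                 tolerance = 1e-12)
  }

  ## points around a ring come back in consecutive angular order
  set.seed(32)
  th <- sort(runif(40, 0, 2 * pi))
  ring <- cbind(cos(th), sin(th)) * 100
  ord2 <- mstOrder(ring)
  steps <- diff(match(ord2, seq_along(th)))
  expect_true(all(abs(steps) == 1) || sum(abs(steps) != 1) <= 1)
})

test_that("principal curves reproduce straight lines exactly", {
  t <- seq(0, 100, length.out = 30)
  pts <- cbind(t, 2 * t + 5)
  pc <- fitPrincipalCurve(pts, df = 8)
  expect_lt(pc@residual, 1e-6)
  ends <- pc@curve[c(1, nrow(pc@curve)), ]
  expect_lt(min(sqrt(rowSums((ends - matrix(pts[1, ], 2, 2, byrow = TRUE))^2))), 1)
  expect_lt(min(sqrt(rowSums((ends - matrix(pts[30, ], 2, 2, byrow = TRUE))^2))), 1)
})

test_that("principal curves track a noisy three-quarter circle", {
  set.seed(33)
  th <- sort(runif(200, 0, 1.5 * pi))
  pts <- cbind(100 * cos(th), 100 * sin(th)) +
    matrix(rnorm(400, 0, 2), ncol = 2)
  pc <- fitPrincipalCurve(pts, df = 8)
  proj <- bruteMinDistToPolyline(pts, pc@curve)
  expect_lte(mean(proj), 3)
  ## residual trace is non-increasing
  expect_true(all(diff(pc@residualTrace) <= 1e-9 * (1 + pc@residualTrace[-1])))

  ## bias-variance: less flexible fits cannot do better
  resids <- vapply(c(8, 6, 4, 2), function(dfk)
    fitPrincipalCurve(pts, df = dfk)@residual, numeric(1))
  expect_true(all(diff(resids) >= -1e-8))
})

test_that("principal curve degenerate and small-sample handling", {
  expect_error(fitPrincipalCurve(matrix(1, 5, 2), df = 8), "identical")
  expect_warning(pc <- fitPrincipalCurve(cbind(1:6, (1:6)^1.3), df = 8),
                 "lowered")
  expect_equal(pc@df, 5)
  pc3 <- fitPrincipalCurve(cbind(c(0, 1, 2), c(0, 0.5, 0)), df = 8)
  expect_equal(nrow(pc3@curve), 3L)
})

test_that("band membership equals brute-force polyline distance", {
  set.seed(34)
  poly <- cbind(cumsum(runif(50, 2, 12)), cumsum(rnorm(50, 0, 6)))
  band <- expandBand(poly, halfWidth = 10)
  pts <- cbind(runif(1000, -20, max(poly[, 1]) + 20),
               runif(1000, min(poly[, 2]) - 40, max(poly[, 2]) + 40))
  expect_identical(bandContains(band, pts),
                   bruteMinDistToPolyline(pts, poly) <= 10)
})

test_that("band boundary is inclusive at exactly the half-width", {
  band <- expandBand(cbind(c(0, 100), c(0, 0)), halfWidth = 10)
  expect_true(bandContains(band, cbind(50, 0)))
  expect_equal(as.vector(bandContains(band, cbind(c(50, 50), c(10, 10.5)))),
               c(TRUE, FALSE))
})

test_that("band membership is invariant under rigid motion", {
  set.seed(35)
  poly <- cbind(seq(0, 120, length.out = 25),
                20 * sin(seq(0, 3, length.out = 25)))
  pts <- cbind(runif(300, -10, 130), runif(300, -40, 40))
  base <- bandContains(expandBand(poly, 10), pts)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi); shift <- runif(2, -50, 50)
    moved <- bandContains(expandBand(rigidTransform(poly, th, shift), 10),
                          rigidTransform(pts, th, shift))
    expect_identical(moved, base)
  }
})

test_that("oversized sparse glands become CE and their cells relabel", {
  ## 320x320 gland (102,400 px) with 2 basal-positive cells: ratio 51,200
  m <- matrix(1L, 320, 320)
  mask <- GlandMask(m)
  df <- makeCellDF(6)
  df$x <- c(50, 250, 60, 150, 250, 100)
  df$y <- c(50, 250, 200, 150, 60, 250)
  tab <- makeTable(df)
  tab <- setCellColumn(tab, "cell_type",
                       c("N-CE", "N-CE", "CE", "CE", "CE", "CE"))
  tab <- assignCellsToGlands(tab, mask)
  res <- classifyGlands(tab, mask)
  expect_equal(res$glands$gland_label, "CE")
  expect_true(all(cellData(res$table)$cell_type_final == "CE"))
})

test_that("ring glands classify N-CE with rim cells kept in the band", {
  core <- simulateCore(smallCoreConfig(seed = 36L, ceFraction = 0))
  tab <- normalizeLog2(applyQC(core$table)$table)
  cls <- suppressWarnings(classifyCells(tab))
  tab2 <- assignCellsToGlands(cls$table, core$mask)
  res <- suppressWarnings(classifyGlands(tab2, core$mask))
  expect_true(all(res$glands$gland_label == "N-CE"))
  conf <- epithelialConfusion(res$table, core$truth, "cell_type_final")
  expect_gt(conf$sens, 0.85)
})

test_that("glands without epithelial cells are excluded", {
  m <- matrix(0L, 40, 40); m[5:15, 5:15] <- 1L; m[25:35, 25:35] <- 2L
  mask <- GlandMask(m)
  df <- makeCellDF(2, compartment = "stromal", cell_area = 400)
  df$x <- c(10, 30); df$y <- c(10, 30)
  tab <- makeTable(df)
  tab <- setCellColumn(tab, "cell_type", c("stroma", "stroma"))
  tab <- assignCellsToGlands(tab, mask)
  res <- classifyGlands(tab, mask)
  expect_true(all(res$glands$gland_label == "excluded"))
})

test_that("gland labels on synthetic cohorts match truth", {
  ## default-scale cores, mixtures fitted pooled across the cohort (the
  ## cohort-mode default): gland calls must track the generator truth
  ch <- simulateCohort(4, coresPerPatient = 1, seed = 41L)
  fits <- suppressWarnings(fitCohortMixtures(ch$cores))
  hits <- 0L; total <- 0L
  for (nm in names(ch$cores)) {
    res <- suppressWarnings(runCorePipeline(ch$cores[[nm]], fits = fits))
    gl <- merge(res$glands,
                ch$cores[[nm]]$truth$glands[, c("gland_id", "true_label")])
    hits <- hits + sum(gl$gland_label == gl$true_label)
    total <- total + nrow(gl)
  }
  expect_gte(hits / total, 0.95)
})
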