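test_that("cell-to-gland distances follow Euclidean geometry and scale", {
  expect_equal(cellToGlandDistance(cbind(5, 5), cbind(5, 5)), 0)
  ## 3-4-5 triangle at 0.325 um per pixel
  expect_equal(cellToGlandDistance(cbind(3, 4), cbind(0, 0)), 5 * 0.325)
  expect_equal(cellToGlandDistance(cbind(3, 4), cbind(0, 0), umPerPx = 1), 5)

  set.seed(51)
  cells <- matrix(runif(200, 0, 500), 100, 2)
  cents <- matrix(runif(20, 0, 500), 10, 2)
  got <- cellToGlandDistance(cells, cents, umPerPx = 1)
  brute <- apply(cells, 1, function(p)
    min(apply(cents, 1, function(q) sqrt(sum((p - q)^2)))))
  expect_equal(got, brute, tolerance = 1e-12)

  expect_identical(cellToGlandDistance(matrix(numeric(0), 0, 2), cents),
                   numeric(0))
  expect_true(all(is.na(cellToGlandDistance(cells,
                                            matrix(numeric(0), 0, 2)))))
})

test_that("radius clustering chains neighbors and drops small groups", {
  pts <- rbind(cbind(rnorm(10, 0, 1), rnorm(10, 0, 1)),
               cbind(rnorm(8, 50, 1), rnorm(8, 50, 1)),
               c(200, 200))
  cl <- clusterPoints(pts, eps = 10, minPts = 5)
  expect_equal(sort(unique(cl)), c(0L, 1L, 2L))
  expect_equal(cl[19], 0L)
  expect_true(all(cl[1:10] == cl[1]) && all(cl[11:18] == cl[11]))
  expect_equal(clusterPoints(pts[1:3, ], eps = 10, minPts = 5), rep(0L, 3))
})

test_that("alpha shapes recover triangles and hulls for large alpha", {
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  shp <- alphaShape(tri, alpha = 100)
  expect_equal(shp$area, 6)    # shoelace of the 3-4-5 right triangle
  set.seed(52)
  pts <- matrix(runif(60, 0, 100), 30, 2)
  shp2 <- alphaShape(pts, alpha = 1e4)
  h <- chull(pts)
  hullArea <- polygonArea(pts[h, ])
  expect_equal(shp2$area, hullArea, tolerance = 1e-9)
})

test_that("alpha shapes of an annulus carve the hole out of the area", {
  set.seed(53)
  th <- runif(600, 0, 2 * pi)
  r <- runif(600, 80, 100)
  ann <- cbind(r * cos(th), r * sin(th))
  shp <- alphaShape(ann, alpha = 15)
  hullArea <- polygonArea(ann[chull(ann), ])
  expect_false(shp$hull)
  expect_gt(length(shp$holes), 0)
  expect_lt(shp$area, 0.75 * hullArea)
  ## rough agreement with the true annulus area
  expect_lt(abs(shp$area - pi * (100^2 - 80^2)) / (pi * (100^2 - 80^2)), 0.25)
})

test_that("MD regions respect the minimum cluster size", {
  set.seed(54)
  clump <- cbind(rnorm(12, 100, 8), rnorm(12, 100, 8))
  strays <- cbind(c(300, 500, 700), c(300, 500, 700))
  regs <- mdRegions(rbind(clump, strays), alpha = 30, minPts = 5)
  expect_length(regs, 1L)
  expect_setequal(regs[[1]]$indices, 1:12)
  expect_gt(regs[[1]]$area_px, 0)
  expect_length(mdRegions(strays, alpha = 30, minPts = 5), 0L)
  expect_error(mdRegions(clump, alpha = -1), "positive")
})

test_that("region-to-gland distances handle overlap and gaps", {
  sq <- function(x0, y0, s) rbind(c(x0, y0), c(x0 + s, y0),
                                  c(x0 + s, y0 + s), c(x0, y0 + s))
  inner <- sq(40, 40, 10); outer <- sq(0, 0, 100)
  r <- regionToGlandDistance(inner, outer)
  expect_equal(r$distance_um, 0)
  expect_true(r$infiltrating)

  ## two unit squares separated by a 7 px gap
  a <- sq(0, 0, 1); b <- sq(8, 0, 1)
  r2 <- regionToGlandDistance(a, b)
  expect_equal(r2$distance_um, 7 * 0.325)
  expect_false(r2$infiltrating)
  ## symmetry
  expect_equal(regionToGlandDistance(b, a)$distance_um, r2$distance_um)

  expect_error(regionToGlandDistance(rbind(c(0, 0), c(1, 1)), outer),
               "3 distinct")
})

test_that("polygon distances match dense boundary sampling", {
  set.seed(55)
  mkpoly <- function(cx, cy, r) {
    th <- sort(runif(12, 0, 2 * pi))
    cbind(cx + r * (1 + 0.2 * sin(3 * th)) * cos(th),
          cy + r * (1 + 0.2 * sin(3 * th)) * sin(th))
  }
  sampleBoundary <- function(poly, k = 600) {
    poly <- rbind(poly, poly[1, ])
    t(sapply(seq_len(k), function(i) {
      j <- sample(nrow(poly) - 1, 1); u <- runif(1)
      poly[j, ] + u * (poly[j + 1, ] - poly[j, ])
    }))
  }
  for (i in 1:4) {
    a <- mkpoly(0, 0, 20); b <- mkpoly(90 + 10 * i, 0, 20)
    got <- regionToGlandDistance(a, b, umPerPx = 1)$distance_um
    sa <- sampleBoundary(a); sb <- sampleBoundary(b)
    brute <- min(sqrt(outer(sa[, 1], sb[, 1], "-")^2 +
                      outer(sa[, 2], sb[, 2], "-")^2))
    expect_lte(got, brute + 1e-9)     # sampling can only overestimate
    expect_lt(brute - got, 0.6)       # and not by more than the spacing
  }
})

test_that("infiltration agrees between edge-crossing and containment tests", {
  set.seed(56)
  sq <- function(x0, y0, s) rbind(c(x0, y0), c(x0 + s, y0),
                                  c(x0 + s, y0 + s), c(x0, y0 + s))
  for (i in 1:20) {
    a <- sq(runif(1, 0, 60), runif(1, 0, 60), runif(1, 5, 30))
    b <- sq(30, 30, 25)
    byEdges <- any(vapply(1:4, function(ii) any(vapply(1:4, function(jj) {
      A <- rbind(a, a[1, ]); B <- rbind(b, b[1, ])
      glandmark:::.segsIntersect(A[ii, ], A[ii + 1, ], B[jj, ], B[jj + 1, ])
    }, logical(1))), logical(1)))
    byContain <- all(glandmark:::.pointsInPolygon(a, rbind(b, b[1, ]))) ||
                 all(glandmark:::.pointsInPolygon(b, rbind(a, a[1, ])))
    expect_identical(polygonsIntersect(a, b), byEdges || byContain)
  }
})

test_that("mask boundaries enclose the label's pixels", {
  core <- simulateCore(smallCoreConfig(seed = 57L))
  gid <- glandIds(core$mask)[1]
  ring <- maskGlandBoundary(core$mask, gid)
  area <- unname(glandAreas(core$mask)[as.character(gid)])
  expect_lt(abs(polygonArea(ring) - area) / area, 0.05)
  idx <- which(maskLabels(core$mask) == gid, arr.ind = TRUE)
  pix <- cbind(idx[, "col"] - 1, idx[, "row"] - 1)
  d <- sqrt(glandmark:::.pointsToSegmentsMinD2(pix, ring))
  inside <- glandmark:::.pointsInPolygon(pix, ring)
  expect_gt(mean(inside | d <= 1), 0.999)
  expect_error(maskGlandBoundary(core$mask, 999L), "not present")
})

test_that("distances and areas transform correctly under similarity maps", {
  set.seed(58)
  cells <- matrix(runif(60, 0, 200), 30, 2)
  cents <- matrix(runif(10, 0, 200), 5, 2)
  ring1 <- cbind(50 + 20 * cos(seq(0, 2 * pi, length.out = 30)),
                 50 + 20 * sin(seq(0, 2 * pi, length.out = 30)))
  ring2 <- ring1 + 120
  d0 <- cellToGlandDistance(cells, cents, umPerPx = 1)
  r0 <- regionToGlandDistance(ring1, ring2, umPerPx = 1)$distance_um
  a0 <- alphaShape(cells, alpha = 60)$area
  ## rigid motion: everything invariant
  th <- 0.83; sh <- c(31, -17)
  expect_equal(cellToGlandDistance(rigidTransform(cells, th, sh),
                                   rigidTransform(cents, th, sh),
                                   umPerPx = 1), d0, tolerance = 1e-9)
  expect_equal(regionToGlandDistance(rigidTransform(ring1, th, sh),
                                     rigidTransform(ring2, th, sh),
                                     umPerPx = 1)$distance_um,
               r0, tolerance = 1e-9)
  expect_equal(alphaShape(rigidTransform(cells, th, sh), alpha = 60)$area,
               a0, tolerance = 1e-6)
  ## scaling by c: distances scale by c, areas by c^2
  cc <- 2.5
  expect_equal(cellToGlandDistance(cells * cc, cents * cc, umPerPx = 1),
               cc * d0, tolerance = 1e-9)
  expect_equal(regionToGlandDistance(ring1 * cc, ring2 * cc,
                                     umPerPx = 1)$distance_um,
               cc * r0, tolerance = 1e-9)
  expect_equal(alphaShape(cells * cc, alpha = 60 * cc)$area,
               cc^2 * a0, tolerance = 1e-6)
})

test_that("patient summaries are medians, log-means and tallies", {
  mkf <- function(pid, usable, treg, th, areas, infil)
    list(core_id = paste0(pid, "_c"), patient_id = pid, usable = usable,
         treg_dist_um = treg, th_dist_um = th, md_area_px = areas,
         md_dist_um = rep(0, length(infil)), md_infiltrating = infil,
         n_ce_glands = if (usable) 1L else 0L, regions = list())
  fs <- list(
    mkf("pA", TRUE, c(10, 20, 100), c(5, 15), exp(2), c(TRUE, FALSE)),
    mkf("pA", TRUE, 40, numeric(0), exp(4), TRUE),
    mkf("pB", TRUE, numeric(0), 8, numeric(0), logical(0)),
    mkf("pC", FALSE, 1, 1, 1, TRUE))
  expect_warning(out <- summarizePatients(fs), "pC")
  pa <- out[out$patient_id == "pA", ]
  expect_equal(pa$median_treg_dist_um, median(c(10, 20, 100, 40)))
  expect_equal(pa$median_th_dist_um, 10)
  expect_equal(pa$log_mean_md_area, 3)   # mean of log(e^2), log(e^4)
  expect_equal(pa$infiltration_count, 2L)
  expect_equal(pa$n_usable_cores, 2L)
  pb <- out[out$patient_id == "pB", ]
  expect_true(is.na(pb$median_treg_dist_um))
  expect_equal(pb$median_th_dist_um, 8)
  expect_false("pC" %in% out$patient_id)
})
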