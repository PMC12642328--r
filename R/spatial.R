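#' @include AllClasses.R
NULL

## ---- polygon primitives (0-based pixel coordinates, x = col, y = row) ----

## Signed shoelace area of a ring (matrix, closed or open).
.shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area by the shoelace formula
#'
#' @param poly m x 2 vertex matrix (closed or open ring).
#' @return absolute enclosed area.
#' @export
polygonArea <- function(poly) abs(.shoelace(as.matrix(poly)))

## Ray-casting point-in-polygon; boundary points count as inside.
.pointsInPolygon <- function(pts, poly) {
  pts <- as.matrix(pts); poly <- as.matrix(poly)
  n <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    j <- i
  }
  ## boundary tolerance: points within 1e-9 of an edge are inside
  d <- .pointsToSegmentsMinD2(pts, poly[c(seq_len(n), 1), , drop = FALSE])
  inside | sqrt(d) < 1e-9
}

## Min squared distance of each point to the segments of a polyline.
.pointsToSegmentsMinD2 <- function(pts, poly) {
  px <- pts[, 1]; py <- pts[, 2]
  ax <- poly[-nrow(poly), 1]; ay <- poly[-nrow(poly), 2]
  bx <- poly[-1, 1]; by <- poly[-1, 2]
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  best <- rep(Inf, length(px))
  for (j in seq_along(ax)) {
    if (len2[j] == 0) {
      d2 <- (px - ax[j])^2 + (py - ay[j])^2
    } else {
      u <- pmin(pmax(((px - ax[j]) * vx[j] + (py - ay[j]) * vy[j]) / len2[j],
                     0), 1)
      d2 <- (px - (ax[j] + u * vx[j]))^2 + (py - (ay[j] + u * vy[j]))^2
    }
    best <- pmin(best, d2)
  }
  best
}

## Do segments (p1,p2) and (p3,p4) intersect (touching counts)?
.segsIntersect <- function(p1, p2, p3, p4) {
  o <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(v) < 1e-12) 0 else sign(v)
  }
  on_seg <- function(a, b, c)
    min(a[1], b[1]) - 1e-12 <= c[1] && c[1] <= max(a[1], b[1]) + 1e-12 &&
    min(a[2], b[2]) - 1e-12 <= c[2] && c[2] <= max(a[2], b[2]) + 1e-12
  o1 <- o(p1, p2, p3); o2 <- o(p1, p2, p4)
  o3 <- o(p3, p4, p1); o4 <- o(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(p1, p2, p3)) || (o2 == 0 && on_seg(p1, p2, p4)) ||
  (o3 == 0 && on_seg(p3, p4, p1)) || (o4 == 0 && on_seg(p3, p4, p2))
}

.closeRing <- function(poly) {
  poly <- as.matrix(poly)
  if (any(poly[1, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

#' Do two polygons intersect or contain one another?
#'
#' Checked by two independent predicates: any pair of boundary edges
#' intersects, or a vertex of one polygon lies inside the other.
#'
#' @param a,b vertex matrices (>= 3 vertices each).
#' @return logical.
#' @export
polygonsIntersect <- function(a, b) {
  a <- .closeRing(a); b <- .closeRing(b)
  if (any(.pointsInPolygon(a[1, , drop = FALSE], b)) ||
      any(.pointsInPolygon(b[1, , drop = FALSE], a))) return(TRUE)
  for (i in seq_len(nrow(a) - 1)) {
    for (j in seq_len(nrow(b) - 1)) {
      if (.segsIntersect(a[i, ], a[i + 1, ], b[j, ], b[j + 1, ]))
        return(TRUE)
    }
  }
  FALSE
}

## Min distance between the boundaries of two (non-intersecting) rings.
.ringDistance <- function(a, b) {
  a <- .closeRing(a); b <- .closeRing(b)
  sqrt(min(.pointsToSegmentsMinD2(a, b), .pointsToSegmentsMinD2(b, a)))
}

## ---- cell-centric distances ----

#' Distance from each T cell to the nearest CE gland centroid
#'
#' The cell-centric ("point view") feature: the shortest Euclidean distance
#' from each T cell to the centroid of the nearest cancerous gland,
#' converted from pixels to micrometres.
#'
#' @param cells n x 2 matrix of T-cell coordinates (px).
#' @param centroids m x 2 matrix of CE gland centroids (px).
#' @param umPerPx physical pixel size (default 0.325 um/px).
#' @return numeric vector of distances in micrometres; all-\code{NA} when
#'   there is no CE gland centroid; empty for zero cells.
#' @export
cellToGlandDistance <- function(cells, centroids, umPerPx = 0.325) {
  cells <- as.matrix(cells)
  if (!nrow(cells)) return(numeric(0))
  if (is.null(centroids) || !nrow(as.matrix(centroids)))
    return(rep(NA_real_, nrow(cells)))
  centroids <- as.matrix(centroids)
  d2 <- outer(cells[, 1], centroids[, 1], "-")^2 +
        outer(cells[, 2], centroids[, 2], "-")^2
  sqrt(apply(d2, 1, min)) * umPerPx
}

## ---- density clustering + alpha shapes ----

#' Radius-based spatial clustering
#'
#' Single-linkage clustering: points within \code{eps} of each other are
#' chained into one cluster; clusters with fewer than \code{minPts} members
#' are labeled 0 (noise).
#'
#' @param pts n x 2 coordinate matrix.
#' @param eps linking radius (px).
#' @param minPts minimum cluster size.
#' @return integer cluster label per point (0 = noise).
#' @export
clusterPoints <- function(pts, eps, minPts = 5L) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (!n) return(integer(0))
  if (n == 1L) return(if (minPts <= 1L) 1L else 0L)
  d <- as.matrix(stats::dist(pts))
  adj <- d <= eps
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  keep <- as.integer(names(sizes)[sizes >= minPts])
  out <- integer(n)
  for (i in seq_along(keep)) out[comp == keep[i]] <- i
  out
}

#' Alpha-shape boundary of a point cluster
#'
#' Classical alpha shape with probe-disk radius \code{alpha}: a pair of
#' points at distance <= 2 alpha forms a boundary edge iff one of the two
#' discs of radius alpha through both points contains no other point.
#' Boundary edges are assembled into closed rings; the region is the
#' largest ring, with any rings nested inside it treated as holes whose
#' area is subtracted. Falls back to the convex hull when the boundary
#' does not assemble into clean rings (e.g. alpha too small for the point
#' spacing) or when it fails to enclose all points.
#'
#' @param pts n x 2 coordinate matrix (n >= 3, not all collinear).
#' @param alpha probe radius (px); must be positive.
#' @return list: \code{outer} (closed ring matrix), \code{holes} (list of
#'   rings), \code{area} (outer area minus hole areas), \code{hull}
#'   (logical: did it fall back to the convex hull?).
#' @export
alphaShape <- function(pts, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) stop("alpha shape needs at least 3 points")
  hullShape <- function() {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    ring <- .closeRing(pts[h, , drop = FALSE])
    list(outer = ring, holes = list(), area = polygonArea(ring), hull = TRUE)
  }
  d <- as.matrix(stats::dist(pts))
  edges <- which(upper.tri(d) & d <= 2 * alpha & d > 0, arr.ind = TRUE)
  if (!nrow(edges)) return(hullShape())
  boundary <- matrix(integer(0), 0, 2)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    mid <- (pts[i, ] + pts[j, ]) / 2
    half <- d[i, j] / 2
    h <- sqrt(max(alpha^2 - half^2, 0))
    v <- (pts[j, ] - pts[i, ]) / d[i, j]
    nrm <- c(-v[2], v[1])
    others <- setdiff(seq_len(n), c(i, j))
    empty <- FALSE
    for (s in c(1, -1)) {
      ctr <- mid + s * h * nrm
      dd <- sqrt((pts[others, 1] - ctr[1])^2 + (pts[others, 2] - ctr[2])^2)
      if (all(dd >= alpha - 1e-9)) { empty <- TRUE; break }
    }
    if (empty) boundary <- rbind(boundary, c(i, j))
  }
  if (!nrow(boundary)) return(hullShape())
  ## assemble rings: every boundary vertex must have degree exactly 2
  deg <- tabulate(boundary, nbins = n)
  verts <- which(deg > 0)
  if (any(deg[verts] != 2L)) return(hullShape())
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_len(nrow(boundary))) {
    i <- boundary[e, 1]; j <- boundary[e, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  unvisited <- rep(TRUE, n)
  rings <- list()
  for (start in verts) {
    if (!unvisited[start]) next
    ring <- start; unvisited[start] <- FALSE
    cur <- start; prev <- 0L
    repeat {
      nxt <- setdiff(adj[[cur]], prev)[1]
      if (is.na(nxt)) return(hullShape())
      if (nxt == start) break
      ring <- c(ring, nxt); unvisited[nxt] <- FALSE
      prev <- cur; cur <- nxt
    }
    if (length(ring) >= 3) rings[[length(rings) + 1L]] <- ring
  }
  if (!length(rings)) return(hullShape())
  areas <- vapply(rings, function(r) polygonArea(pts[r, , drop = FALSE]),
                  numeric(1))
  outer_i <- which.max(areas)
  outer <- .closeRing(pts[rings[[outer_i]], , drop = FALSE])
  if (!all(.pointsInPolygon(pts, outer))) return(hullShape())
  holes <- list(); hole_area <- 0
  for (k in seq_along(rings)) {
    if (k == outer_i) next
    ring <- .closeRing(pts[rings[[k]], , drop = FALSE])
    if (all(.pointsInPolygon(ring[-nrow(ring), , drop = FALSE], outer))) {
      holes[[length(holes) + 1L]] <- ring
      hole_area <- hole_area + areas[k]
    }
  }
  list(outer = outer, holes = holes, area = areas[outer_i] - hole_area,
       hull = FALSE)
}

#' Build macrophage-dense (MD) regions
#'
#' Clusters CD68+ cell coordinates by radius-\code{alpha} linkage, then
#' wraps each cluster of at least \code{minPts} points in an alpha-shape
#' polygon; the region area is computed by the shoelace formula (holes
#' subtracted). Clusters with degenerate geometry (zero area) are dropped.
#'
#' @param pts n x 2 matrix of CD68+ cell coordinates (px).
#' @param alpha probe radius and clustering eps (px; default 30, about one
#'   cell-neighborhood diameter).
#' @param minPts minimum cluster size (default 5).
#' @return list of regions, each a list with \code{region_id},
#'   \code{indices} (rows of \code{pts}), \code{polygon} (outer ring),
#'   \code{holes}, \code{area_px}.
#' @export
mdRegions <- function(pts, alpha = 30, minPts = 5L) {
  if (alpha <= 0) stop("alpha must be positive")
  pts <- as.matrix(pts)
  if (!nrow(pts)) return(list())
  cl <- clusterPoints(pts, eps = alpha, minPts = max(minPts, 3L))
  out <- list()
  for (k in seq_len(max(cl, 0L))) {
    idx <- which(cl == k)
    shp <- tryCatch(alphaShape(pts[idx, , drop = FALSE], alpha),
                    error = function(e) NULL)
    if (is.null(shp) || shp$area <= 0) next
    out[[length(out) + 1L]] <-
      list(region_id = length(out) + 1L, indices = idx,
           polygon = shp$outer, holes = shp$holes, area_px = shp$area)
  }
  out
}

#' Boundary polygon of one gland mask label
#'
#' Traces the oriented contour of the label's pixel region and returns it
#' as a closed ring in 0-based pixel coordinates. When the label has
#' several connected components the largest contour is used.
#'
#' @param mask a \linkS4class{GlandMask}.
#' @param glandId positive mask label.
#' @return closed ring matrix (x = col, y = row, 0-based).
#' @export
maskGlandBoundary <- function(mask, glandId) {
  lab <- maskLabels(mask)
  bin <- lab == glandId
  if (!any(bin)) stop("gland label ", glandId, " not present in mask")
  cont <- EBImage::ocontour(EBImage::Image(t(bin)))
  lens <- vapply(cont, nrow, integer(1))
  ring <- cont[[which.max(lens)]]
  colnames(ring) <- c("x", "y")
  .closeRing(ring)
}

#' Region-centric distance: MD region to CE gland boundary
#'
#' The shape-view feature: the shortest boundary-to-boundary distance
#' between an MD-region polygon and a CE gland boundary polygon, in
#' micrometres. The distance is 0 — an infiltration event — when the
#' polygons intersect or one contains the other.
#'
#' @param region polygon matrix of the MD region (>= 3 vertices).
#' @param gland polygon matrix of the gland boundary (>= 3 vertices).
#' @param umPerPx physical pixel size.
#' @return list: \code{distance_um}, \code{infiltrating} (logical).
#' @export
regionToGlandDistance <- function(region, gland, umPerPx = 0.325) {
  region <- as.matrix(region); gland <- as.matrix(gland)
  if (nrow(unique(region)) < 3 || nrow(unique(gland)) < 3)
    stop("geometry error: polygons need at least 3 distinct vertices")
  if (polygonsIntersect(region, gland))
    return(list(distance_um = 0, infiltrating = TRUE))
  list(distance_um = .ringDistance(region, gland) * umPerPx,
       infiltrating = FALSE)
}

## ---- per-core orchestration and patient summaries ----

#' Compute spatial features for one classified core
#'
#' Extracts the three feature families from a core that has final cell
#' labels and gland labels: T-cell (T_reg, T_H) distances to the nearest
#' CE gland centroid, MD-region areas and boundary distances to the nearest
#' CE gland, and infiltration events. A core is usable only when it has at
#' least one CE gland.
#'
#' @param x the \linkS4class{CellTable} with a per-cell \code{phenotype}
#'   column (see \code{\link{assignImmunePhenotypes}}).
#' @param glands gland data.frame from \code{\link{classifyGlands}}.
#' @param mask the \linkS4class{GlandMask}.
#' @param alpha,minPts MD-region parameters (see \code{\link{mdRegions}}).
#' @param umPerPx physical pixel size.
#' @return list: \code{core_id}, \code{patient_id}, \code{usable},
#'   \code{treg_dist_um}, \code{th_dist_um}, \code{md_area_px},
#'   \code{md_dist_um}, \code{md_infiltrating}, \code{n_ce_glands},
#'   \code{regions}.
#' @export
coreSpatialFeatures <- function(x, glands, mask, alpha = 30, minPts = 5L,
                                umPerPx = pixelSize(mask)) {
  df <- cellData(x)
  if (is.null(df$phenotype)) stop("table lacks a 'phenotype' column")
  ce <- glands[glands$gland_label == "CE", , drop = FALSE]
  usable <- nrow(ce) > 0
  centroids <- if (usable) cbind(ce$centroid_x, ce$centroid_y) else NULL
  tcells <- function(ph) {
    sel <- df$phenotype == ph & !is.na(df$phenotype)
    cellToGlandDistance(cbind(df$x[sel], df$y[sel]), centroids, umPerPx)
  }
  mac <- df$phenotype == "macrophage" & !is.na(df$phenotype)
  regions <- mdRegions(cbind(df$x[mac], df$y[mac]), alpha, minPts)
  md_dist <- numeric(0); md_inf <- logical(0)
  if (length(regions) && usable) {
    bounds <- lapply(ce$gland_id, function(g) maskGlandBoundary(mask, g))
    for (r in regions) {
      dd <- vapply(bounds, function(b)
        regionToGlandDistance(r$polygon, b, umPerPx)$distance_um, numeric(1))
      md_dist <- c(md_dist, min(dd))
      md_inf <- c(md_inf, min(dd) == 0)
    }
  }
  list(core_id = coreId(x), patient_id = patientId(x), usable = usable,
       treg_dist_um = tcells("T_reg"), th_dist_um = tcells("T_H"),
       md_area_px = vapply(regions, `[[`, numeric(1), "area_px"),
       md_dist_um = md_dist, md_infiltrating = md_inf,
       n_ce_glands = nrow(ce), regions = regions)
}

#' Patient-level feature summaries
#'
#' Pools each patient's usable cores and summarizes: T-cell distances by
#' the median, MD-region areas by the mean of natural-log areas, and
#' infiltration events (distance 0) by their count. Patients with no
#' usable core are dropped with a warning; a patient with no T cells of a
#' phenotype gets a missing median for that phenotype.
#'
#' @param coreFeatures list of \code{\link{coreSpatialFeatures}} results.
#' @param clinical optional clinical data.frame
#'   (\code{\link{readClinicalTable}}) merged onto the summaries.
#' @return data.frame: patient_id, median_treg_dist_um, median_th_dist_um,
#'   log_mean_md_area, infiltration_count, n_usable_cores (+ clinical
#'   columns when supplied).
#' @export
summarizePatients <- function(coreFeatures, clinical = NULL) {
  usable <- Filter(function(f) isTRUE(f$usable), coreFeatures)
  dropped <- setdiff(unique(vapply(coreFeatures, `[[`, character(1),
                                   "patient_id")),
                     unique(vapply(usable, `[[`, character(1), "patient_id")))
  if (length(dropped))
    warning("patient(s) with no usable core dropped: ",
            paste(dropped, collapse = ", "))
  pids <- unique(vapply(usable, `[[`, character(1), "patient_id"))
  rows <- lapply(pids, function(p) {
    fs <- Filter(function(f) f$patient_id == p, usable)
    pool <- function(field) unlist(lapply(fs, `[[`, field))
    treg <- pool("treg_dist_um"); th <- pool("th_dist_um")
    areas <- pool("md_area_px")
    data.frame(
      patient_id = p,
      median_treg_dist_um = if (length(treg[!is.na(treg)]))
        stats::median(treg, na.rm = TRUE) else NA_real_,
      median_th_dist_um = if (length(th[!is.na(th)]))
        stats::median(th, na.rm = TRUE) else NA_real_,
      log_mean_md_area = if (length(areas)) mean(log(areas)) else NA_real_,
      infiltration_count = sum(pool("md_infiltrating")),
      n_usable_cores = length(fs),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(clinical)) out <- merge(out, clinical, by = "patient_id",
                                       sort = TRUE)
  out
}
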