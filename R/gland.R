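#' @include AllClasses.R
NULL

#' Assign cells to glands by mask lookup
#'
#' Each cell receives the mask label at its rounded pixel position
#' (0-based coordinates: x = column, y = row); background and out-of-bounds
#' cells receive gland id 0 (out-of-bounds with a warning).
#'
#' @param x a \linkS4class{CellTable}.
#' @param mask a \linkS4class{GlandMask}.
#' @return the table with a \code{gland_id} column.
#' @export
assignCellsToGlands <- function(x, mask) {
  df <- cellData(x)
  lab <- maskLabels(mask)
  row <- round(df$y) + 1L
  col <- round(df$x) + 1L
  oob <- row < 1L | row > nrow(lab) | col < 1L | col > ncol(lab)
  if (any(oob))
    warning(sum(oob), " cell(s) outside the mask bounds; assigned gland_id 0")
  gid <- integer(nrow(df))
  inb <- !oob
  gid[inb] <- lab[cbind(row[inb], col[inb])]
  setCellColumn(x, "gland_id", gid)
}

#' Tabulate glands: area, cell membership, N-CE counts
#'
#' One row per mask label with its pixel area, centroid, member-cell count
#' and number of member cells currently labeled N-CE. Requires
#' \code{gland_id} (from \code{\link{assignCellsToGlands}}) and
#' \code{cell_type} (from \code{\link{classifyCells}}) columns.
#'
#' @param x a labeled \linkS4class{CellTable}.
#' @param mask the corresponding \linkS4class{GlandMask}.
#' @return data.frame: gland_id, area_px, centroid_x, centroid_y, n_cells,
#'   n_epithelial, n_nce.
#' @export
glandTable <- function(x, mask) {
  df <- cellData(x)
  if (is.null(df$gland_id)) stop("run assignCellsToGlands() first")
  if (is.null(df$cell_type)) stop("run classifyCells() first")
  ids <- glandIds(mask)
  areas <- glandAreas(mask)
  cent <- glandCentroids(mask)
  cnt <- function(cond) {
    t <- table(factor(df$gland_id[cond], levels = ids))
    as.integer(t)
  }
  data.frame(
    gland_id = ids,
    area_px = as.integer(areas[as.character(ids)]),
    centroid_x = cent$x[match(ids, cent$gland_id)],
    centroid_y = cent$y[match(ids, cent$gland_id)],
    n_cells = cnt(rep(TRUE, nrow(df))),
    n_epithelial = cnt(df$compartment == "epithelial"),
    n_nce = cnt(df$cell_type == "N-CE"))
}

#' Gland eligibility by the pixels-per-N-CE-cell ratio
#'
#' A gland is eligible for principal-curve fitting iff it contains at least
#' one N-CE cell and its pixel area divided by its N-CE cell count does not
#' exceed \code{threshold} (default 25,000 px per cell). Oversized glands
#' with few scattered basal-positive cells — typically cancerous glands —
#' are excluded from curve fitting and become candidates for CE labeling.
#'
#' @param glands data.frame from \code{\link{glandTable}}.
#' @param threshold maximum area-to-N-CE-count ratio (px per cell).
#' @return the data.frame with \code{ratio} and logical \code{eligible}
#'   columns.
#' @export
filterGlandsByRatio <- function(glands, threshold = 25000) {
  ratio <- ifelse(glands$n_nce > 0, glands$area_px / glands$n_nce, Inf)
  glands$ratio <- ratio
  glands$eligible <- glands$n_nce >= 1L & ratio <= threshold
  glands
}

#' Order points along a minimum spanning tree
#'
#' Builds the Euclidean MST of the points, takes its longest simple path
#' (the tree diameter, found by double traversal), and inserts each
#' off-path point into the ordering at the position of its nearest path
#' vertex. The result is a single continuous ordering along the gland
#' contour — a permutation of the input indices.
#'
#' @param points n x 2 coordinate matrix (n >= 2).
#' @return integer vector: input row indices in path order.
#' @export
mstOrder <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("ordering error: need at least 2 points")
  if (n == 2L) return(1:2)
  d <- as.matrix(stats::dist(points))
  tree <- .buildMST(d)
  dt <- igraph::distances(tree)
  ## double traversal: farthest vertex from vertex 1, then farthest from it
  a <- which.max(dt[1, ])
  b <- which.max(dt[a, ])
  path <- as.integer(igraph::shortest_paths(tree, from = a, to = b,
                                            output = "vpath")$vpath[[1]])
  off <- setdiff(seq_len(n), path)
  if (length(off)) {
    ## nearest path vertex (tree distance); insert after it, nearest first
    ins <- vapply(off, function(v) path[which.min(dt[v, path])], integer(1))
    ord <- order(match(ins, path), d[cbind(off, ins)], off)
    off <- off[ord]; ins <- ins[ord]
    out <- integer(0)
    for (p in path) {
      out <- c(out, p, off[ins == p])
    }
    path <- out
  }
  path
}

## Euclidean minimum spanning tree from a full distance matrix.
.buildMST <- function(d) {
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  igraph::mst(g)
}

## Project points onto a polyline; returns arc-length parameter and squared
## distance of each point's nearest position on the polyline.
.projectToPolyline <- function(points, poly) {
  px <- points[, 1]; py <- points[, 2]
  ax <- poly[-nrow(poly), 1]; ay <- poly[-nrow(poly), 2]
  bx <- poly[-1, 1]; by <- poly[-1, 2]
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  seglen <- sqrt(len2)
  cum <- c(0, cumsum(seglen))
  n <- length(px); m <- length(ax)
  best_d2 <- rep(Inf, n); best_t <- numeric(n)
  for (j in seq_len(m)) {
    if (len2[j] == 0) {
      d2 <- (px - ax[j])^2 + (py - ay[j])^2
      tj <- rep(cum[j], n)
    } else {
      u <- pmin(pmax(((px - ax[j]) * vx[j] + (py - ay[j]) * vy[j]) / len2[j],
                     0), 1)
      d2 <- (px - (ax[j] + u * vx[j]))^2 + (py - (ay[j] + u * vy[j]))^2
      tj <- cum[j] + u * seglen[j]
    }
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_t[upd] <- tj[upd]
  }
  list(t = best_t, d2 = best_d2)
}

#' Fit a principal curve through ordered points
#'
#' Alternates (i) cubic smoothing-spline fits of x(t) and y(t) against the
#' current arc-length parameters at \code{df} degrees of freedom with
#' (ii) re-projection of the points onto the sampled curve to update the
#' parameters, minimizing the mean squared projection distance. Iteration
#' stops when the residual improves by less than \code{tol} (relative), the
#' iteration cap is reached, or a step fails to decrease the residual (the
#' previous iterate is kept, so the recorded residual trace is
#' non-increasing). For fewer than \code{df + 1} points the degrees of
#' freedom are lowered to n - 1 with a warning; for fewer than 4 points the
#' curve is the ordered polyline through the points themselves.
#'
#' @param points n x 2 matrix in MST path order (see \code{\link{mstOrder}}).
#' @param df smoothing degrees of freedom (default 8).
#' @param maxIter maximum projection/smoothing iterations.
#' @param tol relative residual-change tolerance.
#' @param curveSamples number of vertices in the sampled curve polyline.
#' @return a \linkS4class{PrincipalCurve}.
#' @export
fitPrincipalCurve <- function(points, df = 8, maxIter = 20L, tol = 1e-4,
                              curveSamples = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("principal-curve fit error: need at least 2 points")
  if (max(stats::dist(points)) == 0)
    stop("principal-curve fit error: all points identical")
  if (n < 4L) {
    t0 <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
    return(new("PrincipalCurve", points = points, t = t0, curve = points,
               df = n - 1, residual = 0, residualTrace = 0,
               converged = TRUE))
  }
  if (df > n - 1) {
    warning("df lowered from ", df, " to ", n - 1, " for ", n, " points")
    df <- n - 1
  }
  if (is.null(curveSamples)) curveSamples <- max(10L * n, 100L)
  ## initial parameter: cumulative chord length along the given ordering
  t_cur <- c(0, cumsum(sqrt(rowSums(diff(points)^2))))
  ## guard against duplicate consecutive points (zero-length steps)
  t_cur <- t_cur + seq(0, 1e-9, length.out = n)
  best <- NULL
  trace <- numeric(0)
  resid_prev <- Inf
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    sx <- stats::smooth.spline(t_cur, points[, 1], df = df)
    sy <- stats::smooth.spline(t_cur, points[, 2], df = df)
    tt <- seq(min(t_cur), max(t_cur), length.out = curveSamples)
    curve <- cbind(stats::predict(sx, tt)$y, stats::predict(sy, tt)$y)
    proj <- .projectToPolyline(points, curve)
    resid <- mean(proj$d2)
    if (resid > resid_prev) break       # keep previous iterate: monotone trace
    trace <- c(trace, resid)
    best <- list(t = proj$t, curve = curve, resid = resid)
    if (is.finite(resid_prev) &&
        (resid_prev - resid) < tol * (1 + resid_prev)) {
      converged <- TRUE
      break
    }
    resid_prev <- resid
    ord <- order(proj$t)
    points <- points[ord, , drop = FALSE]   # keep points sorted by t
    t_cur <- proj$t[ord]
    t_cur <- t_cur + seq(0, 1e-9, length.out = n)
  }
  ## final consistent (points, t) pairing on the accepted curve
  proj_f <- .projectToPolyline(points, best$curve)
  ord_f <- order(proj_f$t)
  new("PrincipalCurve", points = points[ord_f, , drop = FALSE],
      t = proj_f$t[ord_f], curve = best$curve,
      df = df, residual = best$resid, residualTrace = trace,
      converged = converged)
}

#' Expand a principal curve into a fixed-width band
#'
#' The band is the Euclidean dilation of the curve polyline by
#' \code{halfWidth} pixels (round caps): a cell belongs to the band iff its
#' distance to the polyline is at most \code{halfWidth}, boundary inclusive.
#'
#' @param curve a \linkS4class{PrincipalCurve} (or an m x 2 polyline).
#' @param halfWidth band half-width in pixels (default 10).
#' @return a \linkS4class{BandShape}.
#' @export
expandBand <- function(curve, halfWidth = 10) {
  poly <- if (is(curve, "PrincipalCurve")) curve@curve else as.matrix(curve)
  new("BandShape", polyline = poly, halfWidth = halfWidth)
}

#' Band membership test
#'
#' @param band a \linkS4class{BandShape}.
#' @param points n x 2 coordinate matrix.
#' @return logical vector: distance to the polyline <= half-width?
#' @export
bandContains <- function(band, points) {
  points <- as.matrix(points)
  if (!nrow(points)) return(logical(0))
  proj <- .projectToPolyline(points, band@polyline)
  sqrt(proj$d2) <= band@halfWidth
}

#' Classify glands and finalize cell labels
#'
#' Runs the full gland stage on a classified core: tabulates glands,
#' applies the area-per-N-CE-cell eligibility ratio, orders each eligible
#' gland's N-CE cells along the MST, fits the principal curve, expands it
#' into a band, and assigns final labels. An eligible gland with a fitted
#' curve is an N-CE gland: its member epithelial cells inside the band are
#' (re)labeled N-CE, those outside the band CE. An ineligible gland with at
#' least one epithelial cell is a CE gland and all its epithelial cells are
#' labeled CE. Glands with no epithelial cells are excluded. Cells outside
#' every gland keep their mixture-model labels.
#'
#' @param x a \linkS4class{CellTable} with \code{cell_type} and
#'   \code{gland_id} columns.
#' @param mask the \linkS4class{GlandMask}.
#' @param ratioThreshold eligibility threshold (px per N-CE cell).
#' @param df principal-curve smoothing degrees of freedom.
#' @param bandHalfWidth band half-width in pixels.
#' @return list with \code{table} (the \linkS4class{CellTable} with a
#'   \code{cell_type_final} column), \code{glands} (data.frame with
#'   \code{gland_label} in CE/N-CE/excluded and curve \code{residual}),
#'   \code{curves} and \code{bands} (named lists per N-CE gland).
#' @export
classifyGlands <- function(x, mask, ratioThreshold = 25000, df = 8,
                           bandHalfWidth = 10) {
  gl <- filterGlandsByRatio(glandTable(x, mask), ratioThreshold)
  df_cells <- cellData(x)
  final <- df_cells$cell_type
  gl$gland_label <- "excluded"
  gl$residual <- NA_real_
  curves <- list(); bands <- list()
  for (i in seq_len(nrow(gl))) {
    gid <- gl$gland_id[i]
    member <- df_cells$gland_id == gid
    epi <- member & df_cells$compartment == "epithelial"
    if (!any(epi)) next                       # no epithelial cells: excluded
    if (gl$eligible[i]) {
      nce <- member & df_cells$cell_type == "N-CE"
      pts <- cbind(df_cells$x[nce], df_cells$y[nce])
      curve <- tryCatch({
        ord <- mstOrder(pts)
        fitPrincipalCurve(pts[ord, , drop = FALSE], df = df)
      }, error = function(e) NULL)
      if (is.null(curve)) {                   # degenerate geometry: CE call
        gl$gland_label[i] <- "CE"
        final[epi] <- "CE"
        next
      }
      band <- expandBand(curve, bandHalfWidth)
      gl$gland_label[i] <- "N-CE"
      gl$residual[i] <- curve@residual
      inband <- bandContains(band, cbind(df_cells$x, df_cells$y))
      final[epi & inband] <- "N-CE"
      final[epi & !inband] <- "CE"
      key <- as.character(gid)
      curves[[key]] <- curve
      bands[[key]] <- band
    } else {
      gl$gland_label[i] <- "CE"
      final[epi] <- "CE"
    }
  }
  list(table = setCellColumn(x, "cell_type_final", final),
       glands = gl, curves = curves, bands = bands)
}
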