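#' @include AllClasses.R gmm.R
NULL

.SIM_MARKERS <- c("p63", "CK5", "AMACR", "CD3", "CD4", "CD8", "CD68", "FOXP3")

## Deterministic named RNG substreams: each generation sub-step draws from
## its own seed derived from (seed, name), so adding cells of one type does
## not perturb the draws of another.
.subSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
.withSubstream <- function(seed, name, expr) {
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed(.subSeed(seed, name))
  expr
}

#' Configuration for one synthetic tissue core
#'
#' Describes a square core image containing ring-shaped benign glands (an
#' N-CE basal rim around an empty lumen), lumenless CE-filled glands,
#' scattered stromal cells, and immune cells placed at configurable
#' distances from gland boundaries. Marker intensities are drawn from a
#' two-component Gaussian model in log2 space (background vs foreground),
#' matching the generative model assumed by the mixture-gating classifier.
#' Default foreground and background means are separated by exactly 4
#' pooled standard deviations (the well-separated regime).
#'
#' Default geometry is on the physical pixel scale of 0.325 um/px: gland
#' radii of 100--160 px (about 30--50 um), a basal rim of 12 px (about
#' 4 um), and cell spacings of 25--28 px (8--9 um cell diameters), so the
#' default gland areas and cell densities are the regime in which the
#' 25,000 px-per-N-CE-cell gland eligibility ratio is meaningful.
#'
#' @param imageSize side length of the square core in pixels.
#' @param nGlands number of glands to place.
#' @param glandRadius radius range (px) sampled uniformly per gland.
#' @param rimWidth width of the basal rim (px); must be below the smallest
#'   radius.
#' @param ceFraction fraction of glands that are cancerous (no basal rim).
#' @param boundaryWobble list(amp, waves): sinusoidal boundary perturbation
#'   R(theta) = r (1 + amp sin(waves * theta + phase)).
#' @param markerParams named list per marker of
#'   \code{list(bg = c(mean, sd), fg = c(mean, sd))} in log2 space.
#' @param basalSpacing arc spacing (px) of basal rim cells.
#' @param ceCellSpacing approximate spacing (px) of CE cells filling a
#'   cancerous gland.
#' @param stromalDensity stromal cells per background pixel.
#' @param immuneCounts named counts of \code{T_H}, \code{T_reg} cells.
#' @param immuneDistance \code{c(mean, sd)} (px) of the normal distance from
#'   the nearest gland boundary at which T cells are placed (truncated >= 2).
#' @param mdClusters number of macrophage-dense clusters.
#' @param mdClusterSize macrophages per cluster.
#' @param mdClusterSd spatial spread (px) of a cluster.
#' @param mdDistance \code{c(mean, sd)} (px) of cluster-center distance from
#'   the nearest gland boundary; negative draws put clusters inside glands
#'   (infiltration).
#' @param umPerPx physical pixel size (micrometres).
#' @param seed RNG seed for the core.
#' @return a list of class \code{simCoreConfig}.
#' @export
simCoreConfig <- function(imageSize = 1200L, nGlands = 5L,
                          glandRadius = c(100, 160), rimWidth = 12,
                          ceFraction = 0.6,
                          boundaryWobble = list(amp = 0.06, waves = 5),
                          markerParams = NULL,
                          basalSpacing = 25, ceCellSpacing = 28,
                          stromalDensity = 2.5e-4,
                          immuneCounts = c(T_H = 40, T_reg = 15),
                          immuneDistance = c(mean = 160, sd = 60),
                          mdClusters = 4L, mdClusterSize = 15L,
                          mdClusterSd = 35,
                          mdDistance = c(mean = 30, sd = 60),
                          umPerPx = 0.325, seed = 1L) {
  if (is.null(markerParams)) {
    ## 5 pooled sd between background and foreground: the separation regime
    ## reproducing the ~99% specificity operating point of basal-marker
    ## gating in prostate tissue
    sd0 <- 0.7
    one <- list(bg = c(mean = 2, sd = sd0), fg = c(mean = 2 + 5 * sd0, sd = sd0))
    markerParams <- setNames(rep(list(one), length(.SIM_MARKERS)), .SIM_MARKERS)
  }
  if (ceFraction < 0 || ceFraction > 1) stop("ceFraction must lie in [0, 1]")
  if (min(glandRadius) <= rimWidth)
    stop("gland radii must exceed the rim width")
  structure(list(imageSize = as.integer(imageSize), nGlands = as.integer(nGlands),
                 glandRadius = glandRadius, rimWidth = rimWidth,
                 ceFraction = ceFraction, boundaryWobble = boundaryWobble,
                 markerParams = markerParams, basalSpacing = basalSpacing,
                 ceCellSpacing = ceCellSpacing, stromalDensity = stromalDensity,
                 immuneCounts = immuneCounts, immuneDistance = immuneDistance,
                 mdClusters = as.integer(mdClusters),
                 mdClusterSize = as.integer(mdClusterSize),
                 mdClusterSd = mdClusterSd, mdDistance = mdDistance,
                 umPerPx = umPerPx, seed = as.integer(seed)),
            class = "simCoreConfig")
}

## Boundary radius of gland g at angle theta.
.glandRadiusAt <- function(g, theta) {
  g$r * (1 + g$amp * sin(g$waves * theta + g$phase))
}

## TRUE if points (x, y) lie inside gland g (strictly star-shaped boundary).
.insideGland <- function(g, x, y) {
  dx <- x - g$cx; dy <- y - g$cy
  sqrt(dx^2 + dy^2) <= .glandRadiusAt(g, atan2(dy, dx))
}

.insideAnyGland <- function(glands, x, y) {
  if (!length(glands)) return(rep(FALSE, length(x)))
  Reduce(`|`, lapply(glands, .insideGland, x = x, y = y))
}

## Place non-overlapping gland geometries by rejection sampling.
.placeGlands <- function(cfg) {
  glands <- list()
  margin <- 8
  tries <- 0L
  while (length(glands) < cfg$nGlands) {
    tries <- tries + 1L
    if (tries > 3000L)
      stop("could not place ", cfg$nGlands, " non-overlapping glands; ",
           "use fewer or smaller glands")
    r <- stats::runif(1, cfg$glandRadius[1], cfg$glandRadius[2])
    rmax <- r * (1 + cfg$boundaryWobble$amp)
    cx <- stats::runif(1, rmax + margin, cfg$imageSize - 1 - rmax - margin)
    cy <- stats::runif(1, rmax + margin, cfg$imageSize - 1 - rmax - margin)
    ok <- all(vapply(glands, function(h)
      sqrt((h$cx - cx)^2 + (h$cy - cy)^2) >
        rmax + h$r * (1 + cfg$boundaryWobble$amp) + margin, logical(1)))
    if (ok)
      glands[[length(glands) + 1L]] <-
        list(id = length(glands) + 1L, cx = cx, cy = cy, r = r,
             amp = cfg$boundaryWobble$amp, waves = cfg$boundaryWobble$waves,
             phase = stats::runif(1, 0, 2 * pi))
  }
  glands
}

## Rasterize gland polygons into an integer label image.
.rasterizeGlands <- function(glands, size) {
  lab <- matrix(0L, size, size)
  xs <- 0:(size - 1)
  for (g in glands) {
    rmax <- ceiling(g$r * (1 + abs(g$amp))) + 1L
    cols <- xs[xs >= floor(g$cx) - rmax & xs <= ceiling(g$cx) + rmax]
    rows <- xs[xs >= floor(g$cy) - rmax & xs <= ceiling(g$cy) + rmax]
    px <- expand.grid(x = cols, y = rows)
    inside <- .insideGland(g, px$x, px$y)
    lab[cbind(px$y[inside] + 1L, px$x[inside] + 1L)] <- g$id
  }
  lab
}

## Draw raw linear intensities for n cells of a given true type.
.drawIntensities <- function(n, type, params) {
  fgFor <- switch(type,
    "N-CE" = c("p63", "CK5"),
    "CE" = "AMACR",
    "T_H" = c("CD3", "CD4"),
    "T_reg" = c("CD3", "CD4", "FOXP3"),
    "macrophage" = "CD68",
    character(0))
  m <- matrix(0, n, length(.SIM_MARKERS), dimnames = list(NULL, .SIM_MARKERS))
  for (mk in .SIM_MARKERS) {
    p <- if (mk %in% fgFor) params[[mk]]$fg else params[[mk]]$bg
    v <- stats::rnorm(n, p[["mean"]], p[["sd"]])
    ## raw linear scale chosen so log2(raw + 1) recovers v for v >= 0
    m[, mk] <- pmax(2^v - 1, 0)
  }
  m
}

#' Simulate one tissue core with ground truth
#'
#' Generates a cell table, a gland label mask, and per-cell/per-gland truth
#' for one core: benign (N-CE) glands carry a basal rim of p63/CK5
#' foreground cells around an empty lumen; cancerous (CE) glands are filled
#' with basal-negative, AMACR-positive epithelial cells; stromal cells and
#' immune cells (T_H, T_reg, clustered macrophages) are scattered outside
#' (or, for macrophage clusters, possibly overlapping) the glands. Fully
#' reproducible from \code{cfg$seed}; each sub-step draws from its own
#' named RNG substream.
#'
#' @param cfg a \code{\link{simCoreConfig}}.
#' @param coreId,patientId,gradeGroup metadata stamped on the core.
#' @return list with \code{table} (a \linkS4class{CellTable}, raw
#'   intensities), \code{mask} (a \linkS4class{GlandMask}), and
#'   \code{truth}: list(\code{cells} data.frame(cell_id, true_type,
#'   true_gland), \code{glands} data.frame(gland_id, true_label, cx, cy, r),
#'   \code{boundaries} list of polygon matrices).
#' @export
simulateCore <- function(cfg = simCoreConfig(), coreId = "sim_core",
                         patientId = "sim_patient",
                         gradeGroup = NA_integer_) {
  size <- cfg$imageSize
  glands <- .withSubstream(cfg$seed, "glands", .placeGlands(cfg))
  nCE <- round(cfg$ceFraction * length(glands))
  isCE <- rep(FALSE, length(glands))
  if (nCE > 0) isCE[seq_len(nCE)] <- TRUE   # deterministic: first glands are CE
  mask <- .rasterizeGlands(glands, size)

  pos <- list(); types <- character(0); glandOf <- integer(0)

  ## basal rims of benign glands
  rim <- .withSubstream(cfg$seed, "basal", {
    out <- list()
    for (g in glands[!isCE]) {
      nring <- max(8L, round(2 * pi * g$r / cfg$basalSpacing))
      th <- seq(0, 2 * pi, length.out = nring + 1L)[-1] +
        stats::runif(nring, -0.02, 0.02)
      rad <- .glandRadiusAt(g, th) - cfg$rimWidth / 2 +
        stats::rnorm(nring, 0, cfg$rimWidth / 5)
      ## clamp 1.5 px inside the boundary so rounded pixel centers stay in
      ## the mask label
      rad <- pmin(pmax(rad, .glandRadiusAt(g, th) - cfg$rimWidth + 0.5),
                  .glandRadiusAt(g, th) - 1.5)
      out[[length(out) + 1L]] <-
        cbind(x = g$cx + rad * cos(th), y = g$cy + rad * sin(th),
              gland = g$id)
    }
    out
  })
  for (b in rim) {
    pos[[length(pos) + 1L]] <- b[, 1:2, drop = FALSE]
    types <- c(types, rep("N-CE", nrow(b)))
    glandOf <- c(glandOf, b[, 3])
  }

  ## CE glands: filled with cancerous epithelial cells
  cefill <- .withSubstream(cfg$seed, "ce_fill", {
    out <- list()
    for (g in glands[isCE]) {
      area <- pi * g$r^2
      n <- max(5L, round(area / cfg$ceCellSpacing^2))
      got <- 0L; pts <- matrix(0, 0, 2)
      while (got < n) {
        cand <- cbind(stats::runif(2 * n, -g$r, g$r),
                      stats::runif(2 * n, -g$r, g$r))
        keep <- sqrt(rowSums(cand^2)) <=
          0.93 * .glandRadiusAt(g, atan2(cand[, 2], cand[, 1]))
        cand <- cand[keep, , drop = FALSE]
        take <- min(nrow(cand), n - got)
        pts <- rbind(pts, cand[seq_len(take), , drop = FALSE])
        got <- got + take
      }
      out[[length(out) + 1L]] <-
        cbind(x = g$cx + pts[, 1], y = g$cy + pts[, 2], gland = g$id)
    }
    out
  })
  for (b in cefill) {
    pos[[length(pos) + 1L]] <- b[, 1:2, drop = FALSE]
    types <- c(types, rep("CE", nrow(b)))
    glandOf <- c(glandOf, b[, 3])
  }

  ## stromal cells in the background region
  stroma <- .withSubstream(cfg$seed, "stroma", {
    n <- stats::rpois(1, cfg$stromalDensity * size^2)
    pts <- matrix(numeric(0), 0, 2)
    while (nrow(pts) < n) {
      cand <- cbind(stats::runif(2 * n, 0, size - 1),
                    stats::runif(2 * n, 0, size - 1))
      cand <- cand[!.insideAnyGland(glands, cand[, 1], cand[, 2]), ,
                   drop = FALSE]
      pts <- rbind(pts, cand)
    }
    pts[seq_len(n), , drop = FALSE]
  })
  if (nrow(stroma)) {
    pos[[length(pos) + 1L]] <- stroma
    types <- c(types, rep("stroma", nrow(stroma)))
    glandOf <- c(glandOf, rep(0L, nrow(stroma)))
  }

  ## T cells at configurable distances from gland boundaries
  placeNearGlands <- function(n, dmean, dsd, allowInside = FALSE) {
    pts <- matrix(numeric(0), 0, 2)
    attempts <- 0L
    while (nrow(pts) < n && attempts < 200L * max(n, 1L)) {
      attempts <- attempts + 1L
      if (length(glands)) {
        g <- glands[[sample.int(length(glands), 1L)]]
        th <- stats::runif(1, 0, 2 * pi)
        d <- stats::rnorm(1, dmean, dsd)
        if (!allowInside) d <- max(d, 2)
        rr <- .glandRadiusAt(g, th) + d
        p <- c(g$cx + rr * cos(th), g$cy + rr * sin(th))
      } else {
        p <- stats::runif(2, 0, size - 1)
      }
      if (any(p < 0) || any(p > size - 1)) next
      if (!allowInside && length(glands) &&
          .insideAnyGland(glands, p[1], p[2])) next
      pts <- rbind(pts, p)
    }
    pts
  }
  for (ph in c("T_H", "T_reg")) {
    tc <- .withSubstream(cfg$seed, paste0("tcell_", ph),
      placeNearGlands(cfg$immuneCounts[[ph]], cfg$immuneDistance[["mean"]],
                      cfg$immuneDistance[["sd"]]))
    if (nrow(tc)) {
      pos[[length(pos) + 1L]] <- tc
      types <- c(types, rep(ph, nrow(tc)))
      glandOf <- c(glandOf, rep(0L, nrow(tc)))
    }
  }

  ## macrophage-dense clusters near/overlapping gland boundaries
  mac <- .withSubstream(cfg$seed, "macrophage", {
    centers <- placeNearGlands(cfg$mdClusters, cfg$mdDistance[["mean"]],
                               cfg$mdDistance[["sd"]], allowInside = TRUE)
    out <- matrix(numeric(0), 0, 2)
    for (i in seq_len(nrow(centers))) {
      mpts <- cbind(stats::rnorm(cfg$mdClusterSize, centers[i, 1], cfg$mdClusterSd),
                    stats::rnorm(cfg$mdClusterSize, centers[i, 2], cfg$mdClusterSd))
      mpts <- mpts[mpts[, 1] >= 0 & mpts[, 1] <= size - 1 &
                   mpts[, 2] >= 0 & mpts[, 2] <= size - 1, , drop = FALSE]
      out <- rbind(out, mpts)
    }
    out
  })
  if (nrow(mac)) {
    pos[[length(pos) + 1L]] <- mac
    types <- c(types, rep("macrophage", nrow(mac)))
    glandOf <- c(glandOf, rep(0L, nrow(mac)))
  }

  xy <- do.call(rbind, c(pos, list(matrix(numeric(0), 0, 2))))
  n <- nrow(xy)
  inten <- .withSubstream(cfg$seed, "intensity", {
    m <- matrix(0, n, length(.SIM_MARKERS),
                dimnames = list(NULL, .SIM_MARKERS))
    for (ty in unique(types)) {
      idx <- which(types == ty)
      m[idx, ] <- .drawIntensities(length(idx), ty, cfg$markerParams)
    }
    m
  })
  epithelial <- types %in% c("CE", "N-CE")
  cells <- data.frame(
    cell_id = sprintf("c%05d", seq_len(n)),
    x = if (n) xy[, 1] else numeric(0),
    y = if (n) xy[, 2] else numeric(0),
    compartment = ifelse(epithelial, "epithelial", "stromal"),
    nucleus_count = 1L,
    area_nucleus = 120, area_membrane = 200, area_cytoplasm = 300,
    cell_area = ifelse(epithelial, 700, 400),
    quality_score = 0.95,
    stringsAsFactors = FALSE)
  tab <- CellTable(cells, inten, coreId = coreId, patientId = patientId,
                   gradeGroup = gradeGroup)
  boundaries <- lapply(glands, function(g) {
    th <- seq(0, 2 * pi, length.out = 361L)
    rr <- .glandRadiusAt(g, th)
    cbind(x = g$cx + rr * cos(th), y = g$cy + rr * sin(th))
  })
  truth <- list(
    cells = data.frame(cell_id = cells$cell_id, true_type = types,
                       true_gland = as.integer(glandOf),
                       stringsAsFactors = FALSE),
    glands = data.frame(
      gland_id = vapply(glands, `[[`, integer(1), "id"),
      true_label = ifelse(isCE, "CE", "N-CE"),
      cx = vapply(glands, `[[`, numeric(1), "cx"),
      cy = vapply(glands, `[[`, numeric(1), "cy"),
      r = vapply(glands, `[[`, numeric(1), "r")),
    boundaries = boundaries)
  list(table = tab, mask = GlandMask(mask, umPerPx = cfg$umPerPx),
       truth = truth)
}

#' Simulate a patient cohort with recurrence outcomes
#'
#' Each patient receives a grade group, a latent spatial feature (the mean
#' placement distance, in micrometres, of their T cells from gland
#' boundaries), and a biochemical-recurrence time drawn from an exponential
#' distribution with hazard \code{baseHazard * hazardLink(feature)},
#' administratively censored at \code{censorHorizon} months. With
#' \code{coresPerPatient >= 1}, imaged cores are generated whose immune
#' placement distances realize the patient's feature; with
#' \code{coresPerPatient = 0} only features and outcomes are produced
#' (useful for survival-statistics studies at large n).
#'
#' @param nPatients number of patients (>= 2).
#' @param coresPerPatient imaged cores per patient (0 to skip imaging).
#' @param hazardLink function mapping the feature (micrometres) to a
#'   positive hazard multiplier.
#' @param baseHazard baseline exponential hazard per month.
#' @param censorHorizon administrative censoring time (months).
#' @param gradeProbs sampling probabilities of grade groups 1..3.
#' @param featureMean,featureSd cohort distribution of the latent feature
#'   (micrometres; truncated >= 5).
#' @param coreConfig template \code{\link{simCoreConfig}} for imaged cores.
#' @param seed cohort RNG seed.
#' @return list with \code{clinical} (data.frame: patient_id, grade_group,
#'   bcr_event, bcr_time_months), \code{features} (patient_id,
#'   true_feature_um, hazard), \code{cores} (named list of
#'   \code{\link{simulateCore}} outputs, possibly empty).
#' @export
simulateCohort <- function(nPatients, coresPerPatient = 1L,
                           hazardLink = function(f) ifelse(f >= 50, 2, 1),
                           baseHazard = 0.02, censorHorizon = 60,
                           gradeProbs = c(1, 1, 1) / 3,
                           featureMean = 50, featureSd = 15,
                           coreConfig = simCoreConfig(), seed = 1L) {
  if (nPatients < 2) stop("nPatients must be >= 2")
  pid <- sprintf("p%04d", seq_len(nPatients))
  grade <- .withSubstream(seed, "grade",
    sample.int(3L, nPatients, replace = TRUE, prob = gradeProbs))
  feat <- .withSubstream(seed, "feature",
    pmax(stats::rnorm(nPatients, featureMean, featureSd), 5))
  mult <- hazardLink(feat)
  if (any(!is.finite(mult)) || any(mult <= 0))
    stop("hazardLink must return positive finite multipliers")
  haz <- baseHazard * mult
  raw_t <- .withSubstream(seed, "recurrence",
    stats::rexp(nPatients, rate = haz))
  event <- raw_t <= censorHorizon
  time <- pmin(raw_t, censorHorizon)
  clinical <- data.frame(patient_id = pid, grade_group = grade,
                         bcr_event = event, bcr_time_months = time,
                         stringsAsFactors = FALSE)
  cores <- list()
  if (coresPerPatient >= 1L) {
    for (i in seq_len(nPatients)) {
      for (j in seq_len(coresPerPatient)) {
        cfg <- coreConfig
        cfg$immuneDistance[["mean"]] <- feat[i] / cfg$umPerPx
        cfg$seed <- .subSeed(seed, sprintf("core_%s_%d", pid[i], j))
        cid <- sprintf("%s_core%d", pid[i], j)
        cores[[cid]] <- simulateCore(cfg, coreId = cid, patientId = pid[i],
                                     gradeGroup = grade[i])
      }
    }
  }
  list(clinical = clinical,
       features = data.frame(patient_id = pid, true_feature_um = feat,
                             hazard = haz, stringsAsFactors = FALSE),
       cores = cores)
}
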