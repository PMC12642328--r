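#' @import methods
NULL

## Column names every CellTable carries besides marker intensities/QC.
.CELL_CORE_COLS <- c("cell_id", "x", "y", "compartment", "nucleus_count",
                     "area_nucleus", "area_membrane", "area_cytoplasm",
                     "cell_area", "quality_score")

.COMPARTMENTS <- c("epithelial", "stromal")

#' CellTable: per-cell records for one tissue core
#'
#' The central container of the pipeline: one row per segmented cell with
#' pixel coordinates (0-based, \code{x} = column, \code{y} = row),
#' compartment, QC quantities, and a matrix of per-marker intensities.
#' Intensities are raw (linear) until \code{\link{normalizeLog2}} is applied,
#' after which \code{logTransformed(x)} is \code{TRUE}.
#'
#' @slot cells data.frame with columns \code{cell_id}, \code{x}, \code{y},
#'   \code{compartment}, \code{nucleus_count}, \code{area_nucleus},
#'   \code{area_membrane}, \code{area_cytoplasm}, \code{cell_area},
#'   \code{quality_score}, plus any derived label columns
#'   (\code{cell_type}, \code{gland_id}, ...).
#' @slot intensities numeric matrix, cells x markers.
#' @slot markerQC logical matrix, cells x markers; \code{TRUE} = pass.
#' @slot coreId,patientId single character identifiers.
#' @slot gradeGroup integer grade group (1--3) or \code{NA}.
#' @slot logTransformed logical; have intensities been log2-transformed?
#'
#' @export
setClass("CellTable",
  representation(cells = "data.frame", intensities = "matrix",
                 markerQC = "matrix", coreId = "character",
                 patientId = "character", gradeGroup = "integer",
                 logTransformed = "logical"),
  prototype(coreId = "core", patientId = "patient",
            gradeGroup = NA_integer_, logTransformed = FALSE))

setValidity("CellTable", function(object) {
  msg <- character()
  df <- object@cells
  missing_cols <- setdiff(.CELL_CORE_COLS, names(df))
  if (length(missing_cols))
    msg <- c(msg, paste("cells is missing columns:",
                        paste(missing_cols, collapse = ", ")))
  if (!length(msg)) {
    if (anyDuplicated(df$cell_id))
      msg <- c(msg, "cell_id values must be unique within a core")
    if (!all(df$compartment %in% .COMPARTMENTS))
      msg <- c(msg, "compartment must be 'epithelial' or 'stromal'")
    qs <- df$quality_score
    if (any(is.finite(qs) & (qs < 0 | qs > 1)))
      msg <- c(msg, "quality_score must lie in [0, 1]")
    areas <- df[c("area_nucleus", "area_membrane", "area_cytoplasm", "cell_area")]
    if (any(unlist(areas) < 0, na.rm = TRUE))
      msg <- c(msg, "areas must be nonnegative")
    if (nrow(object@intensities) != nrow(df))
      msg <- c(msg, "intensity matrix rows must match cell rows")
    if (is.null(colnames(object@intensities)) && ncol(object@intensities) > 0)
      msg <- c(msg, "intensity matrix must have marker column names")
    if (!object@logTransformed &&
        any(object@intensities < 0, na.rm = TRUE))
      msg <- c(msg, "raw intensities must be nonnegative")
    if (!identical(dim(object@markerQC), dim(object@intensities)))
      msg <- c(msg, "markerQC must have the same shape as intensities")
  }
  if (length(object@coreId) != 1L || length(object@patientId) != 1L)
    msg <- c(msg, "coreId and patientId must be single strings")
  if (length(msg)) msg else TRUE
})

#' GlandMask: integer label image of glandular structures
#'
#' A 2-D integer matrix in which 0 is background and each positive label k
#' marks the pixels of gland k, together with the physical pixel size.
#'
#' @slot labels integer matrix (rows = y, columns = x).
#' @slot umPerPx physical size of one pixel in micrometres; the default
#'   0.325 corresponds to a 6.5 um camera pixel behind a 20x objective.
#'
#' @export
setClass("GlandMask",
  representation(labels = "matrix", umPerPx = "numeric"),
  prototype(umPerPx = 0.325))

setValidity("GlandMask", function(object) {
  msg <- character()
  lab <- object@labels
  if (!is.integer(lab)) msg <- c(msg, "labels must be an integer matrix")
  else if (any(lab < 0L)) msg <- c(msg, "labels must be nonnegative")
  if (length(object@umPerPx) != 1L || object@umPerPx <= 0)
    msg <- c(msg, "umPerPx must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' MixtureFit: a univariate Gaussian mixture fitted by EM
#'
#' Holds the K-component mixture f(x) = sum_k pi_k N(x | mu_k, sigma_k^2)
#' fitted to one marker's log2 intensities, together with the
#' log-likelihood trace of the EM iterations.
#'
#' @slot K number of components (after any pruning of degenerate ones).
#' @slot weights mixing proportions pi_k, summing to 1.
#' @slot means,variances component parameters mu_k, sigma_k^2.
#' @slot logLik log-likelihood value after each EM iteration (non-decreasing).
#' @slot nIter number of EM iterations performed.
#' @slot converged did the relative log-likelihood change fall below eps?
#' @slot n number of observations used in the fit.
#'
#' @export
setClass("MixtureFit",
  representation(K = "integer", weights = "numeric", means = "numeric",
                 variances = "numeric", logLik = "numeric",
                 nIter = "integer", converged = "logical", n = "integer"))

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (length(object@weights) != object@K ||
      length(object@means) != object@K ||
      length(object@variances) != object@K)
    msg <- c(msg, "weights, means and variances must each have length K")
  if (abs(sum(object@weights) - 1) > 1e-10)
    msg <- c(msg, "mixing proportions must sum to 1 (tolerance 1e-10)")
  if (any(object@variances <= 0))
    msg <- c(msg, "variances must be strictly positive")
  ll <- object@logLik
  if (length(ll) > 1 && any(diff(ll) < -1e-8 * (1 + abs(ll[-length(ll)]))))
    msg <- c(msg, "log-likelihood must be non-decreasing across iterations")
  if (length(msg)) msg else TRUE
})

#' PrincipalCurve: smooth latent backbone of one gland
#'
#' An ordered polyline gamma(t) fitted through the gland's basal (N-CE)
#' cell coordinates by alternating cubic-smoothing-spline fits and
#' projections, minimizing the mean squared orthogonal distance.
#'
#' @slot points the input coordinates in fitting order (n x 2).
#' @slot t arc-length parameter of each input point's projection.
#' @slot curve sampled curve polyline (m x 2, m >= 2).
#' @slot df smoothing degrees of freedom actually used.
#' @slot residual final mean squared projection distance (px^2).
#' @slot residualTrace residual after each iteration (non-increasing).
#' @slot converged logical.
#'
#' @export
setClass("PrincipalCurve",
  representation(points = "matrix", t = "numeric", curve = "matrix",
                 df = "numeric", residual = "numeric",
                 residualTrace = "numeric", converged = "logical"))

setValidity("PrincipalCurve", function(object) {
  msg <- character()
  if (nrow(object@curve) < 2L) msg <- c(msg, "curve polyline needs >= 2 vertices")
  if (object@residual < 0) msg <- c(msg, "residual must be nonnegative")
  rt <- object@residualTrace
  if (length(rt) > 1 && any(diff(rt) > 1e-9 * (1 + rt[-length(rt)])))
    msg <- c(msg, "residual trace must be non-increasing")
  if (is.unsorted(object@t, strictly = FALSE))
    msg <- c(msg, "projection parameters t must be monotone along the ordering")
  if (length(msg)) msg else TRUE
})

#' BandShape: fixed-half-width band around a principal curve
#'
#' The dilation of a curve polyline by a Euclidean half-width (round caps):
#' a point belongs to the band iff its distance to the polyline is at most
#' \code{halfWidth}. Membership is boundary-inclusive.
#'
#' @slot polyline the curve polyline (m x 2).
#' @slot halfWidth half-width in pixels (default 10).
#'
#' @export
setClass("BandShape",
  representation(polyline = "matrix", halfWidth = "numeric"),
  prototype(halfWidth = 10))

setValidity("BandShape", function(object) {
  msg <- character()
  if (nrow(object@polyline) < 2L) msg <- c(msg, "polyline needs >= 2 vertices")
  if (object@halfWidth <= 0) msg <- c(msg, "halfWidth must be positive")
  if (length(msg)) msg else TRUE
})
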