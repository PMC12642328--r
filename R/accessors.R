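#' @include AllClasses.R
NULL

#' Accessors for pipeline containers
#'
#' Small accessor generics used across the package instead of direct slot
#' access: \code{cellData} returns the per-cell data.frame, \code{intensities}
#' the cells x markers matrix, \code{markers} the marker names,
#' \code{markerQC} the pass/fail matrix, \code{nCells} the row count,
#' \code{coreId}/\code{patientId}/\code{gradeGroup} the core metadata, and
#' \code{logTransformed} whether intensities are in log2 space.
#'
#' @param x a \linkS4class{CellTable} (or \linkS4class{GlandMask} for the
#'   mask accessors below).
#' @return See each generic's description.
#' @name accessors
#' @aliases cellData intensities markers markerQC nCells coreId patientId
#'   gradeGroup logTransformed
NULL

#' @rdname accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))
#' @rdname accessors
#' @export
setMethod("cellData", "CellTable", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "CellTable", function(x) x@intensities)

#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))
#' @rdname accessors
#' @export
setMethod("markers", "CellTable", function(x) colnames(x@intensities))

#' @rdname accessors
#' @export
setGeneric("markerQC", function(x) standardGeneric("markerQC"))
#' @rdname accessors
#' @export
setMethod("markerQC", "CellTable", function(x) x@markerQC)

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setMethod("nCells", "CellTable", function(x) nrow(x@cells))

#' @rdname accessors
#' @export
setGeneric("coreId", function(x) standardGeneric("coreId"))
#' @rdname accessors
#' @export
setMethod("coreId", "CellTable", function(x) x@coreId)

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setMethod("patientId", "CellTable", function(x) x@patientId)

#' @rdname accessors
#' @export
setGeneric("gradeGroup", function(x) standardGeneric("gradeGroup"))
#' @rdname accessors
#' @export
setMethod("gradeGroup", "CellTable", function(x) x@gradeGroup)

#' @rdname accessors
#' @export
setGeneric("logTransformed", function(x) standardGeneric("logTransformed"))
#' @rdname accessors
#' @export
setMethod("logTransformed", "CellTable", function(x) x@logTransformed)

#' Subset a CellTable by row
#'
#' @param x a \linkS4class{CellTable}.
#' @param i logical or integer row index.
#' @param j,drop,... ignored (cells are rows; markers are never dropped).
#' @return a \linkS4class{CellTable} with the selected cells.
#' @export
setMethod("[", c("CellTable", "ANY", "missing"), function(x, i, j, ..., drop = FALSE) {
  initialize(x,
    cells = x@cells[i, , drop = FALSE],
    intensities = x@intensities[i, , drop = FALSE],
    markerQC = x@markerQC[i, , drop = FALSE])
})

#' Replace or add a per-cell column
#'
#' Convenience for attaching derived per-cell columns (labels, gland ids)
#' without touching slots directly.
#'
#' @param x a \linkS4class{CellTable}.
#' @param name column name in the per-cell data.frame.
#' @param value replacement vector of length \code{nCells(x)}.
#' @return the updated \linkS4class{CellTable}.
#' @export
setCellColumn <- function(x, name, value) {
  stopifnot(is(x, "CellTable"), length(value) == nCells(x) || length(value) == 1L)
  x@cells[[name]] <- value
  validObject(x)
  x
}

## ---- GlandMask accessors ----

#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setMethod("maskLabels", "GlandMask", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "GlandMask", function(x) x@umPerPx)

#' @rdname accessors
#' @export
setGeneric("glandIds", function(x) standardGeneric("glandIds"))
#' @rdname accessors
#' @export
setMethod("glandIds", "GlandMask", function(x) {
  ids <- sort(unique(as.vector(x@labels)))
  ids[ids > 0L]
})

#' @rdname accessors
#' @export
setGeneric("nGlands", function(x) standardGeneric("nGlands"))
#' @rdname accessors
#' @export
setMethod("nGlands", "GlandMask", function(x) length(glandIds(x)))

#' Per-gland pixel areas and centroids
#'
#' Gland area is the pixel count of the mask label; the centroid is the
#' unweighted mean of the label's 0-based pixel coordinates
#' (x = column, y = row).
#'
#' @param x a \linkS4class{GlandMask}.
#' @return \code{glandAreas}: named integer vector of pixel counts.
#'   \code{glandCentroids}: data.frame with \code{gland_id}, \code{x}, \code{y}.
#' @export
setGeneric("glandAreas", function(x) standardGeneric("glandAreas"))
#' @rdname glandAreas
#' @export
setMethod("glandAreas", "GlandMask", function(x) {
  lab <- x@labels[x@labels > 0L]
  if (!length(lab)) return(setNames(integer(0), character(0)))
  tab <- table(lab)
  setNames(as.integer(tab), names(tab))
})

#' @rdname glandAreas
#' @export
setGeneric("glandCentroids", function(x) standardGeneric("glandCentroids"))
#' @rdname glandAreas
#' @export
setMethod("glandCentroids", "GlandMask", function(x) {
  ids <- glandIds(x)
  if (!length(ids))
    return(data.frame(gland_id = integer(0), x = numeric(0), y = numeric(0)))
  idx <- which(x@labels > 0L, arr.ind = TRUE)
  lab <- x@labels[idx]
  ## 0-based pixel coordinates: x = col - 1, y = row - 1
  cx <- tapply(idx[, "col"] - 1, lab, mean)
  cy <- tapply(idx[, "row"] - 1, lab, mean)
  ord <- match(as.character(ids), names(cx))
  data.frame(gland_id = ids, x = as.numeric(cx[ord]), y = as.numeric(cy[ord]))
})

## ---- show methods ----

setMethod("show", "CellTable", function(object) {
  df <- object@cells
  cat(sprintf("CellTable: %d cells, core '%s', patient '%s'%s\n",
              nrow(df), object@coreId, object@patientId,
              if (is.na(object@gradeGroup)) ""
              else sprintf(", grade group %d", object@gradeGroup)))
  cat(sprintf("  markers (%s): %s\n",
              if (object@logTransformed) "log2" else "raw",
              paste(colnames(object@intensities), collapse = ", ")))
  comp <- table(df$compartment)
  cat("  compartments:", paste(sprintf("%s=%d", names(comp), comp), collapse = ", "), "\n")
  if ("cell_type" %in% names(df)) {
    ty <- table(df$cell_type)
    cat("  cell types:", paste(sprintf("%s=%d", names(ty), ty), collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "GlandMask", function(object) {
  cat(sprintf("GlandMask: %d x %d px, %d glands, %.3f um/px\n",
              nrow(object@labels), ncol(object@labels), nGlands(object),
              object@umPerPx))
  invisible(NULL)
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf("MixtureFit: K = %d, n = %d, %d EM iterations (%s)\n",
              object@K, object@n, object@nIter,
              if (object@converged) "converged" else "max_iter reached"))
  for (k in seq_len(object@K))
    cat(sprintf("  component %d: pi = %.4f, mu = %.4f, sigma2 = %.4f\n",
                k, object@weights[k], object@means[k], object@variances[k]))
  cat(sprintf("  final log-likelihood: %.4f\n", tail(object@logLik, 1)))
  invisible(NULL)
})

setMethod("show", "PrincipalCurve", function(object) {
  cat(sprintf(
    "PrincipalCurve: %d points, df = %g, %d curve vertices, residual = %.4g px^2 (%s)\n",
    nrow(object@points), object@df, nrow(object@curve), object@residual,
    if (object@converged) "converged" else "max_iter reached"))
  invisible(NULL)
})

setMethod("show", "BandShape", function(object) {
  cat(sprintf("BandShape: half-width %g px around a %d-vertex polyline\n",
              object@halfWidth, nrow(object@polyline)))
  invisible(NULL)
})
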