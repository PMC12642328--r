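#' @include AllClasses.R
NULL

#' Cell-level QC configuration
#'
#' Thresholds for the cell-level quality filters applied before
#' classification. Defaults: epithelial cells need 1--2 segmented nuclei;
#' each epithelial sub-compartment (nucleus, membrane, cytoplasm) area must
#' be greater than 10 px but not more than 1500 px; whole-cell area must lie
#' in [50, 3500] px for epithelial and [30, 1500] px for stromal cells; the
#' cyclic-registration quality score must exceed 0.85; and epithelial cells
#' failing marker-specific QC for a basal marker (p63, CK5) are removed
#' before CE/N-CE classification.
#'
#' @param nucleusCountRange integer bounds on epithelial nucleus count.
#' @param subcompartmentAreaRange half-open pixel bounds (lower exclusive,
#'   upper inclusive) on each epithelial sub-compartment area.
#' @param cellAreaEpithelial,cellAreaStromal inclusive whole-cell area bounds.
#' @param qualityThreshold cells are kept when quality score is strictly
#'   above this value.
#' @param qcMarkers markers whose marker-specific QC must pass for
#'   epithelial cells.
#' @return a list of class \code{qcConfig}.
#' @export
qcConfig <- function(nucleusCountRange = c(1L, 2L),
                     subcompartmentAreaRange = c(10, 1500),
                     cellAreaEpithelial = c(50, 3500),
                     cellAreaStromal = c(30, 1500),
                     qualityThreshold = 0.85,
                     qcMarkers = c("p63", "CK5")) {
  ranges <- list(nucleusCountRange = nucleusCountRange,
                 subcompartmentAreaRange = subcompartmentAreaRange,
                 cellAreaEpithelial = cellAreaEpithelial,
                 cellAreaStromal = cellAreaStromal)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] >= r[2])
      stop(nm, ": lower bound must be below upper bound")
  }
  structure(c(ranges, list(qualityThreshold = qualityThreshold,
                           qcMarkers = qcMarkers)),
            class = "qcConfig")
}

#' Apply cell-level QC filters
#'
#' Removes cells failing any of the configured rules and reports per-rule
#' removal counts. A cell can fail several rules; per-rule counts are
#' tallied on the input so they may overlap, and the report's last row gives
#' the total (deduplicated) number removed.
#'
#' @param x a \linkS4class{CellTable} with QC fields populated.
#' @param cfg a \code{\link{qcConfig}}.
#' @return list with \code{table} (filtered \linkS4class{CellTable}) and
#'   \code{report} (data.frame: \code{rule}, \code{removed}).
#' @export
applyQC <- function(x, cfg = qcConfig()) {
  df <- cellData(x)
  epi <- df$compartment == "epithelial"
  fail <- list()
  fail$nucleus_count <- epi & (df$nucleus_count < cfg$nucleusCountRange[1] |
                               df$nucleus_count > cfg$nucleusCountRange[2])
  sr <- cfg$subcompartmentAreaRange
  sub_ok <- df$area_nucleus > sr[1] & df$area_nucleus <= sr[2] &
            df$area_membrane > sr[1] & df$area_membrane <= sr[2] &
            df$area_cytoplasm > sr[1] & df$area_cytoplasm <= sr[2]
  fail$subcompartment_area <- epi & !sub_ok
  bounds_e <- cfg$cellAreaEpithelial; bounds_s <- cfg$cellAreaStromal
  fail$cell_area <- ifelse(epi,
    df$cell_area < bounds_e[1] | df$cell_area > bounds_e[2],
    df$cell_area < bounds_s[1] | df$cell_area > bounds_s[2])
  fail$quality_score <- !(df$quality_score > cfg$qualityThreshold)
  qc <- markerQC(x)
  present <- intersect(cfg$qcMarkers, colnames(qc))
  fail$marker_qc <- epi & if (length(present))
    rowSums(!qc[, present, drop = FALSE]) > 0 else FALSE
  any_fail <- Reduce(`|`, fail)
  report <- data.frame(rule = c(names(fail), "total"),
                       removed = c(vapply(fail, sum, integer(1)),
                                   sum(any_fail)),
                       row.names = NULL)
  if (all(any_fail))
    warning("all cells removed by QC; returning an empty table")
  list(table = x[!any_fail], report = report)
}

#' Log2 transform and per-core median centering of marker intensities
#'
#' Replaces each raw intensity v by log2(v + pseudocount), then (optionally)
#' subtracts the per-marker median over the core so cores are comparable
#' across staining batches. The transform is strictly monotone, so
#' within-core intensity ranks are preserved per marker. An optional upper
#' quantile cap (applied on the raw scale before the transform) stands in
#' for manual review of artifactual intensity outliers; it is off by
#' default.
#'
#' @param x a \linkS4class{CellTable} with raw (linear) intensities.
#' @param pseudocount added before the log (default 1).
#' @param centerByCore subtract the per-marker core median in log2 space?
#' @param capQuantile if non-NULL, winsorize each marker at this upper raw
#'   quantile before transforming (e.g. 0.999).
#' @return the \linkS4class{CellTable} with log2 intensities
#'   (\code{logTransformed(x)} becomes \code{TRUE}).
#' @export
normalizeLog2 <- function(x, pseudocount = 1, centerByCore = TRUE,
                          capQuantile = NULL) {
  if (logTransformed(x))
    stop("intensities are already log2-transformed")
  v <- intensities(x)
  if (any(v < 0, na.rm = TRUE)) {
    bad <- which(rowSums(v < 0, na.rm = TRUE) > 0)[1]
    stop("negative raw intensity for cell '", cellData(x)$cell_id[bad], "'")
  }
  if (!is.null(capQuantile)) {
    for (j in seq_len(ncol(v))) {
      cap <- stats::quantile(v[, j], capQuantile, na.rm = TRUE, names = FALSE)
      v[, j] <- pmin(v[, j], cap)
    }
  }
  v <- log2(v + pseudocount)
  if (centerByCore && nrow(v) > 0) {
    med <- apply(v, 2, stats::median, na.rm = TRUE)
    v <- sweep(v, 2, med, "-")
  }
  x@intensities <- v
  x@logTransformed <- TRUE
  validObject(x)
  x
}
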