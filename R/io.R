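#' @include AllClasses.R
NULL

#' Construct a CellTable
#'
#' @param cells data.frame with the per-cell columns (see
#'   \linkS4class{CellTable}).
#' @param intensities numeric matrix (cells x markers) with marker column
#'   names; raw linear scale unless \code{logTransformed}.
#' @param markerQC optional logical pass/fail matrix of the same shape;
#'   defaults to all-pass.
#' @param coreId,patientId identifiers shared by all cells of the core.
#' @param gradeGroup integer grade group (1--3) or \code{NA}.
#' @param logTransformed are the intensities already in log2 space?
#' @return a validated \linkS4class{CellTable}.
#' @export
CellTable <- function(cells, intensities, markerQC = NULL,
                      coreId = "core", patientId = "patient",
                      gradeGroup = NA_integer_, logTransformed = FALSE) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (is.null(markerQC)) {
    markerQC <- matrix(TRUE, nrow(intensities), ncol(intensities),
                       dimnames = dimnames(intensities))
  }
  cells <- as.data.frame(cells)
  cells$cell_id <- as.character(cells$cell_id)
  rownames(cells) <- NULL
  new("CellTable", cells = cells, intensities = intensities,
      markerQC = markerQC, coreId = as.character(coreId),
      patientId = as.character(patientId),
      gradeGroup = as.integer(gradeGroup),
      logTransformed = isTRUE(logTransformed))
}

#' Construct a GlandMask
#'
#' @param labels integer matrix; 0 = background, k > 0 = gland k.
#' @param umPerPx physical pixel size in micrometres (default 0.325).
#' @return a validated \linkS4class{GlandMask}.
#' @export
GlandMask <- function(labels, umPerPx = 0.325) {
  labels <- as.matrix(labels)
  if (!is.integer(labels)) {
    if (any(abs(labels - round(labels)) > 0, na.rm = TRUE))
      stop("gland mask labels must be integers")
    storage.mode(labels) <- "integer"
  }
  new("GlandMask", labels = labels, umPerPx = umPerPx)
}

#' Column schema for reading cell-table CSV files
#'
#' Maps the canonical per-cell fields to the column names used in a given
#' CSV export, and lists the marker intensity (and optional marker-QC)
#' columns. Defaults match the files written by
#' \code{\link{writeCellTable}}.
#'
#' @param markers character vector of marker names.
#' @param columns named list overriding individual canonical-to-column
#'   mappings (canonical names: \code{cell_id}, \code{x}, \code{y},
#'   \code{compartment}, \code{nucleus_count}, \code{area_nucleus},
#'   \code{area_membrane}, \code{area_cytoplasm}, \code{cell_area},
#'   \code{quality_score}).
#' @param intensityPrefix,qcPrefix prefixes forming the intensity and
#'   marker-QC column names from the marker name.
#' @return a list of class \code{cellTableSchema}.
#' @export
cellTableSchema <- function(markers = c("p63", "CK5", "AMACR", "CD3", "CD4",
                                        "CD8", "CD68", "FOXP3"),
                            columns = list(),
                            intensityPrefix = "intensity_",
                            qcPrefix = "qc_") {
  map <- as.list(setNames(.CELL_CORE_COLS, .CELL_CORE_COLS))
  for (nm in names(columns)) {
    if (!nm %in% .CELL_CORE_COLS)
      stop("unknown canonical field in schema: ", nm)
    map[[nm]] <- columns[[nm]]
  }
  structure(list(markers = markers, columns = map,
                 intensityPrefix = intensityPrefix, qcPrefix = qcPrefix),
            class = "cellTableSchema")
}

#' Read a single-cell table from CSV
#'
#' Reads one core's cell table. Rows whose coordinates cannot be parsed as
#' finite numbers are rejected with their row indices reported in a warning.
#' Marker-QC columns are optional; missing ones default to all-pass.
#'
#' @param path CSV file with a header row.
#' @param schema a \code{\link{cellTableSchema}}.
#' @param coreId,patientId,gradeGroup core metadata (not stored in the CSV
#'   cell rows).
#' @return a \linkS4class{CellTable}.
#' @export
readCellTable <- function(path, schema = cellTableSchema(),
                          coreId = "core", patientId = "patient",
                          gradeGroup = NA_integer_) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- unlist(schema$columns)
  int_cols <- paste0(schema$intensityPrefix, schema$markers)
  missing_cols <- setdiff(c(need, int_cols), names(raw))
  if (length(missing_cols))
    stop("cell table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  xs <- suppressWarnings(as.numeric(raw[[schema$columns$x]]))
  ys <- suppressWarnings(as.numeric(raw[[schema$columns$y]]))
  bad <- which(!is.finite(xs) | !is.finite(ys))
  if (length(bad)) {
    warning("rejected ", length(bad), " row(s) with unparseable coordinates: ",
            paste(bad, collapse = ", "))
    raw <- raw[-bad, , drop = FALSE]
    xs <- xs[-bad]; ys <- ys[-bad]
  }
  cells <- data.frame(
    cell_id = as.character(raw[[schema$columns$cell_id]]),
    x = xs, y = ys,
    compartment = as.character(raw[[schema$columns$compartment]]),
    nucleus_count = as.integer(raw[[schema$columns$nucleus_count]]),
    area_nucleus = as.numeric(raw[[schema$columns$area_nucleus]]),
    area_membrane = as.numeric(raw[[schema$columns$area_membrane]]),
    area_cytoplasm = as.numeric(raw[[schema$columns$area_cytoplasm]]),
    cell_area = as.numeric(raw[[schema$columns$cell_area]]),
    quality_score = as.numeric(raw[[schema$columns$quality_score]]),
    stringsAsFactors = FALSE)
  inten <- as.matrix(raw[, int_cols, drop = FALSE])
  colnames(inten) <- schema$markers
  qc_cols <- paste0(schema$qcPrefix, schema$markers)
  qc <- matrix(TRUE, nrow(inten), ncol(inten), dimnames = dimnames(inten))
  have_qc <- qc_cols %in% names(raw)
  for (j in which(have_qc))
    qc[, j] <- as.logical(raw[[qc_cols[j]]])
  extra <- setdiff(names(raw), c(need, int_cols, qc_cols))
  for (nm in extra) cells[[nm]] <- raw[[nm]]
  CellTable(cells, inten, qc, coreId = coreId, patientId = patientId,
            gradeGroup = gradeGroup)
}

#' Write a CellTable to CSV
#'
#' Inverse of \code{\link{readCellTable}} under the same schema.
#'
#' @param x a \linkS4class{CellTable}.
#' @param path output CSV path.
#' @param schema a \code{\link{cellTableSchema}} (its markers must match
#'   \code{markers(x)}).
#' @return \code{path}, invisibly.
#' @export
writeCellTable <- function(x, path, schema = cellTableSchema(markers = markers(x))) {
  stopifnot(identical(schema$markers, markers(x)))
  df <- x@cells
  names(df)[match(.CELL_CORE_COLS, names(df))] <-
    unlist(schema$columns[.CELL_CORE_COLS])
  inten <- x@intensities
  colnames(inten) <- paste0(schema$intensityPrefix, markers(x))
  qc <- x@markerQC
  colnames(qc) <- paste0(schema$qcPrefix, markers(x))
  out <- cbind(df, as.data.frame(inten), as.data.frame(qc))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a gland label mask
#'
#' Accepts single-channel 8/16-bit integer TIFF or PNG label images
#' (0 = background). Multi-channel or floating-point images are rejected.
#'
#' @param path TIFF (.tif/.tiff) or PNG (.png) file.
#' @param umPerPx physical pixel size in micrometres.
#' @return a \linkS4class{GlandMask}.
#' @export
readGlandMask <- function(path, umPerPx = 0.325) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) != 2L)
      stop("gland mask format error: expected a single-channel image, got ",
           paste(dim(img), collapse = "x"))
    if (!is.integer(img) && any(img != round(img)))
      stop("gland mask format error: floating-point pixel values")
    lab <- matrix(as.integer(img), nrow(img), ncol(img))
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    if (length(dim(img)) != 2L)
      stop("gland mask format error: expected a single-channel image, got ",
           paste(dim(img), collapse = "x"))
    bits <- attr(img, "info")$bit.depth
    if (is.null(bits)) bits <- 8L
    scaled <- img * (2^bits - 1)
    if (max(abs(scaled - round(scaled))) > 1e-6)
      stop("gland mask format error: non-integer pixel values")
    lab <- matrix(as.integer(round(scaled)), nrow(img), ncol(img))
  } else {
    stop("unsupported gland mask format: .", ext)
  }
  GlandMask(lab, umPerPx = umPerPx)
}

#' Write a gland label mask as 16-bit TIFF
#'
#' Labels are stored exactly (verified round-trip) for values up to 65535.
#'
#' @param mask a \linkS4class{GlandMask}.
#' @param path output .tif path.
#' @return \code{path}, invisibly.
#' @export
writeGlandMask <- function(mask, path) {
  lab <- maskLabels(mask)
  if (max(lab) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a per-patient clinical table
#'
#' Expects columns \code{patient_id}, \code{grade_group}, \code{bcr_event}
#' (0/1 biochemical-recurrence flag) and \code{bcr_time_months}.
#'
#' @param path CSV file.
#' @return data.frame with one row per patient.
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "grade_group", "bcr_event", "bcr_time_months")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("clinical table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  df$grade_group <- as.integer(df$grade_group)
  df$bcr_event <- as.logical(df$bcr_event)
  df$bcr_time_months <- as.numeric(df$bcr_time_months)
  if (any(df$bcr_time_months < 0, na.rm = TRUE))
    stop("follow-up times must be nonnegative")
  df
}

#' Write a QC report as CSV
#'
#' @param report the \code{report} data.frame returned by \code{\link{applyQC}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeQCReport <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
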