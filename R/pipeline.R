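#' @include AllClasses.R qc.R gmm.R gland.R spatial.R stats.R synthetic.R
NULL

#' Classify one core end to end
#'
#' Chains the per-core stages: cell-level QC, log2 normalization, mixture
#' gating of the basal markers into CE/N-CE/stroma labels, mixture gating
#' of the immune markers into phenotypes for stromal cells, gland
#' assignment and classification, and spatial feature extraction.
#'
#' @param core list with \code{table} (raw-intensity
#'   \linkS4class{CellTable}) and \code{mask} (\linkS4class{GlandMask}),
#'   e.g. one element of \code{simulateCore()} output.
#' @param qcCfg a \code{\link{qcConfig}}.
#' @param emCfg an \code{\link{emConfig}} for all marker fits.
#' @param basalMarkers markers gated into the CE/N-CE call.
#' @param immuneMarkers markers gated into immune phenotypes.
#' @param ratioThreshold,df,bandHalfWidth gland-stage parameters
#'   (see \code{\link{classifyGlands}}).
#' @param alpha,minPts MD-region parameters (see \code{\link{mdRegions}}).
#' @param thIncludesTreg overlapping T_H convention flag.
#' @param fits optional named list of prefitted \linkS4class{MixtureFit}
#'   objects (basal and/or immune markers), e.g. pooled cohort fits from
#'   \code{\link{fitCohortMixtures}}; missing markers are fitted per core.
#' @return list: \code{table} (final labels), \code{qcReport},
#'   \code{fits}, \code{glands}, \code{curves}, \code{bands},
#'   \code{features} (from \code{\link{coreSpatialFeatures}}).
#' @export
runCorePipeline <- function(core, qcCfg = qcConfig(), emCfg = emConfig(),
                            basalMarkers = c("p63", "CK5"),
                            immuneMarkers = c("CD3", "CD4", "CD8", "CD68",
                                              "FOXP3"),
                            ratioThreshold = 25000, df = 8,
                            bandHalfWidth = 10, alpha = 30, minPts = 5L,
                            thIncludesTreg = FALSE, fits = NULL) {
  qc <- applyQC(core$table, qcCfg)
  tab <- normalizeLog2(qc$table)
  cls <- classifyCells(tab, basalMarkers, emCfg, fits = fits)
  tab <- cls$table
  ## immune gating on stromal cells with the same mixture machinery
  stromal <- cellData(tab)$compartment == "stromal"
  icalls <- matrix(FALSE, nCells(tab), length(immuneMarkers),
                   dimnames = list(NULL, immuneMarkers))
  ifits <- list()
  for (m in immuneMarkers) {
    v <- intensities(tab)[stromal, m]
    ifits[[m]] <- if (!is.null(fits[[m]])) fits[[m]] else fitGmmEM(v, emCfg)
    icalls[stromal, m] <- classifyPositive(v, ifits[[m]])
  }
  pheno <- rep(NA_character_, nCells(tab))
  pheno[stromal] <- assignImmunePhenotypes(
    as.data.frame(icalls[stromal, , drop = FALSE]), thIncludesTreg)
  tab <- setCellColumn(tab, "phenotype", pheno)
  tab <- assignCellsToGlands(tab, core$mask)
  gl <- classifyGlands(tab, core$mask, ratioThreshold, df, bandHalfWidth)
  tab <- gl$table
  feats <- coreSpatialFeatures(tab, gl$glands, core$mask, alpha, minPts)
  list(table = tab, qcReport = qc$report,
       fits = c(cls$fits, ifits), glands = gl$glands,
       curves = gl$curves, bands = gl$bands, features = feats)
}

#' Fit marker mixtures pooled across a cohort's cores
#'
#' Applies QC and log2 normalization to every core, pools the epithelial
#' cells' basal-marker intensities and the stromal cells' immune-marker
#' intensities across cores, and fits one mixture per marker. Because
#' normalization median-centers each core, pooled log2 intensities are
#' comparable across cores; pooling is the cohort-level analogue of
#' fitting per tissue microarray and gives a far more stable gating
#' boundary than per-core fits.
#'
#' @param cores list of cores (each with \code{table} and \code{mask}).
#' @param qcCfg,emCfg,basalMarkers,immuneMarkers as in
#'   \code{\link{runCorePipeline}}.
#' @param ... ignored (absorbs unrelated pipeline arguments).
#' @return named list of \linkS4class{MixtureFit}, one per marker.
#' @export
fitCohortMixtures <- function(cores, qcCfg = qcConfig(), emCfg = emConfig(),
                              basalMarkers = c("p63", "CK5"),
                              immuneMarkers = c("CD3", "CD4", "CD8", "CD68",
                                                "FOXP3"), ...) {
  tabs <- lapply(cores, function(cr) normalizeLog2(applyQC(cr$table, qcCfg)$table))
  pool <- function(marker, compartment) {
    unlist(lapply(tabs, function(t)
      intensities(t)[cellData(t)$compartment == compartment, marker]))
  }
  fits <- list()
  for (m in basalMarkers) fits[[m]] <- fitGmmEM(pool(m, "epithelial"), emCfg)
  for (m in immuneMarkers) fits[[m]] <- fitGmmEM(pool(m, "stromal"), emCfg)
  fits
}

#' Run the whole pipeline on a simulated cohort
#'
#' Simulates a cohort, runs every core through
#' \code{\link{runCorePipeline}}, summarizes patients, and computes the
#' statistical layer: the composition permutation chi-squared by grade
#' (cell types and immune phenotypes, BH-adjusted as one family), AMACR
#' permutation difference tests between CE and N-CE (pooled and per
#' grade), Kruskal-Wallis grade trends of the patient features, and
#' Kaplan-Meier/log-rank tests of the median-dichotomized T-cell
#' distances. When \code{outDir} is given, writes deterministic CSV
#' outputs (cell labels, gland table, patient features, clinical table,
#' statistics, KM curves) plus a plain-text log of filter counts and fit
#' diagnostics.
#'
#' @param seed master seed; every random draw derives from it.
#' @param nPatients,coresPerPatient cohort size.
#' @param coreConfig template \code{\link{simCoreConfig}}; its seed is
#'   overridden per core.
#' @param hazardLink,baseHazard,censorHorizon outcome model (see
#'   \code{\link{simulateCohort}}).
#' @param nPerm permutation count for the permutation tests.
#' @param censorAt administrative censoring horizon for the log-rank tests
#'   (default 60 months, i.e. 5-year recurrence).
#' @param pooledFits fit each marker's mixture once on cells pooled across
#'   all cores (the default) rather than per core; pooling stabilizes the
#'   gating boundary exactly as fitting per tissue-microarray does for
#'   real cohorts.
#' @param outDir optional output directory.
#' @param ... further arguments passed to \code{\link{runCorePipeline}}.
#' @return list: \code{cohort}, \code{cores} (per-core pipeline results),
#'   \code{patients} (feature + clinical data.frame), \code{stats}
#'   (data.frame of test results), \code{km} (named list of
#'   \code{\link{kmLogrank}} results).
#' @export
runAll <- function(seed = 1L, nPatients = 16L, coresPerPatient = 1L,
                   coreConfig = simCoreConfig(imageSize = 900L, nGlands = 4L,
                                              glandRadius = c(90, 130)),
                   hazardLink = function(f) ifelse(f >= 50, 2, 1),
                   baseHazard = 0.02, censorHorizon = 60,
                   nPerm = 10000L, censorAt = 60, pooledFits = TRUE,
                   outDir = NULL, ...) {
  cohort <- simulateCohort(nPatients, coresPerPatient,
                           hazardLink = hazardLink, baseHazard = baseHazard,
                           censorHorizon = censorHorizon,
                           coreConfig = coreConfig, seed = seed)
  fits <- if (pooledFits) fitCohortMixtures(cohort$cores, ...) else NULL
  cores <- lapply(cohort$cores, runCorePipeline, fits = fits, ...)
  feats <- lapply(cores, `[[`, "features")
  patients <- summarizePatients(feats, cohort$clinical)

  ## pooled per-cell table with patient grade attached
  cells <- do.call(rbind, lapply(cores, function(cr) {
    df <- cellData(cr$table)
    data.frame(core_id = coreId(cr$table), patient_id = patientId(cr$table),
               grade_group = gradeGroup(cr$table),
               cell_id = df$cell_id, x = df$x, y = df$y,
               compartment = df$compartment,
               cell_type = df$cell_type_final,
               phenotype = df$phenotype,
               gland_id = df$gland_id,
               amacr_log2 = intensities(cr$table)[, "AMACR"],
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL

  stats_rows <- list()
  addRow <- function(test, statistic, p, family = NA_character_)
    stats_rows[[length(stats_rows) + 1L]] <<-
      data.frame(test = test, statistic = statistic, p.value = p,
                 family = family, stringsAsFactors = FALSE)

  ## composition by grade: cell types, immune phenotypes (one BH family)
  comp <- permutationChisq(cells$grade_group, cells$cell_type,
                           nPerm = nPerm, seed = .subSeed(seed, "chisq_type"))
  addRow("composition_cell_type", comp$statistic, comp$p.value, "composition")
  imm <- cells[!is.na(cells$phenotype) & cells$phenotype != "other", ]
  if (length(unique(imm$grade_group)) >= 2 &&
      length(unique(imm$phenotype)) >= 2) {
    compi <- permutationChisq(imm$grade_group, imm$phenotype, nPerm = nPerm,
                              seed = .subSeed(seed, "chisq_imm"))
    addRow("composition_immune", compi$statistic, compi$p.value, "composition")
  }

  ## AMACR between CE and N-CE, pooled and per grade (one BH family)
  epi <- cells[cells$cell_type %in% c("CE", "N-CE"), ]
  amacr <- permutationDiffTest(epi$amacr_log2[epi$cell_type == "CE"],
                               epi$amacr_log2[epi$cell_type == "N-CE"],
                               nPerm = nPerm,
                               seed = .subSeed(seed, "amacr_pooled"))
  addRow("amacr_pooled", amacr$statistic, amacr$p.value, "amacr")
  for (g in sort(unique(epi$grade_group))) {
    sub <- epi[epi$grade_group == g, ]
    if (!all(c("CE", "N-CE") %in% sub$cell_type)) next
    tst <- permutationDiffTest(sub$amacr_log2[sub$cell_type == "CE"],
                               sub$amacr_log2[sub$cell_type == "N-CE"],
                               nPerm = nPerm,
                               seed = .subSeed(seed, paste0("amacr_g", g)))
    addRow(paste0("amacr_grade", g), tst$statistic, tst$p.value, "amacr")
  }
  fold <- logFoldChange(2^epi$amacr_log2[epi$cell_type == "CE"],
                        2^epi$amacr_log2[epi$cell_type == "N-CE"])
  addRow("amacr_fold_change", fold$fold, NA_real_)

  ## grade trends of patient features
  for (f in c("median_treg_dist_um", "median_th_dist_um",
              "log_mean_md_area", "infiltration_count")) {
    v <- patients[[f]]
    g <- patients$grade_group
    if (length(unique(g[!is.na(v)])) >= 2) {
      kw <- kruskalWallis(v, g)
      addRow(paste0("kw_", f), kw$statistic, kw$p.value, "trend")
    }
  }

  ## KM / log-rank on median-dichotomized T-cell distances
  km <- list()
  for (f in c("median_treg_dist_um", "median_th_dist_um")) {
    v <- patients[[f]]
    if (sum(is.finite(v)) < 4) next
    split <- dichotomizeByMedian(v)
    res <- tryCatch(
      kmLogrank(patients$bcr_time_months, patients$bcr_event,
                split$group, censorAt = censorAt),
      error = function(e) NULL)
    if (!is.null(res)) {
      km[[f]] <- c(res, list(cutoff = split$cutoff))
      addRow(paste0("logrank_", f), res$statistic, res$p.value, "survival")
    }
  }

  stats_df <- do.call(rbind, c(stats_rows, list(make.row.names = FALSE)))
  stats_df$q.value <- NA_real_
  for (fam in unique(stats_df$family)) {
    if (is.na(fam)) next
    sel <- !is.na(stats_df$family) & stats_df$family == fam
    stats_df$q.value[sel] <- bhAdjust(stats_df$p.value[sel])
  }

  out <- list(cohort = cohort, cores = cores, patients = patients,
              stats = stats_df, km = km)
  if (!is.null(outDir)) .writeRunAll(out, cells, outDir)
  out
}

## Deterministic CSV outputs + structured log.
.writeRunAll <- function(out, cells, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 12,
                                                   format = "g"))
    df
  }
  utils::write.csv(fmt(cells), file.path(outDir, "cell_labels.csv"),
                   row.names = FALSE)
  glands <- do.call(rbind, lapply(names(out$cores), function(nm) {
    g <- out$cores[[nm]]$glands
    cbind(core_id = nm, g)
  }))
  utils::write.csv(fmt(glands), file.path(outDir, "gland_table.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt(out$patients),
                   file.path(outDir, "patient_features.csv"),
                   row.names = FALSE)
  utils::write.csv(fmt(out$cohort$clinical),
                   file.path(outDir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(fmt(out$stats), file.path(outDir, "stats_results.csv"),
                   row.names = FALSE)
  kmrows <- do.call(rbind, lapply(names(out$km), function(nm) {
    fit <- out$km[[nm]]$fit
    data.frame(feature = nm,
               group = rep(names(fit$strata), fit$strata),
               time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               survival = fit$surv, stringsAsFactors = FALSE)
  }))
  if (!is.null(kmrows))
    utils::write.csv(fmt(kmrows), file.path(outDir, "km_curves.csv"),
                     row.names = FALSE)
  log_lines <- c(
    sprintf("cores processed: %d", length(out$cores)),
    sprintf("patients summarized: %d", nrow(out$patients)),
    unlist(lapply(names(out$cores), function(nm) {
      cr <- out$cores[[nm]]
      rep_str <- paste(sprintf("%s=%d", cr$qcReport$rule, cr$qcReport$removed),
                       collapse = ", ")
      fit_str <- paste(vapply(names(cr$fits), function(m) {
        f <- cr$fits[[m]]
        sprintf("%s(iter=%d,conv=%s)", m, f@nIter, f@converged)
      }, character(1)), collapse = ", ")
      c(sprintf("[%s] qc removals: %s", nm, rep_str),
        sprintf("[%s] em fits: %s", nm, fit_str),
        sprintf("[%s] glands: %s", nm,
                paste(sprintf("%d:%s", cr$glands$gland_id,
                              cr$glands$gland_label), collapse = ", ")))
    })))
  writeLines(log_lines, file.path(outDir, "run_log.txt"))
  invisible(outDir)
}
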