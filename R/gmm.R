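#' @include AllClasses.R
NULL

#' EM configuration for marker gating
#'
#' @param eps relative log-likelihood convergence tolerance (default 1e-8).
#' @param maxIter maximum EM iterations (default 1000).
#' @param K number of mixture components (2 or 3 in typical use; K = 1 is
#'   the plain Gaussian MLE).
#' @param init initialization strategy: \code{"quantile"} places component
#'   means at the (2k-1)/(2K) sample quantiles with equal weights and
#'   pooled variance (deterministic); \code{"kmeans"} uses a seeded k-means.
#' @param varFloor variance floor as a fraction of the total sample
#'   variance, preventing singular components.
#' @param seed RNG seed used only by the \code{"kmeans"} init.
#' @return a list of class \code{emConfig}.
#' @export
emConfig <- function(eps = 1e-8, maxIter = 1000L, K = 2L,
                     init = c("quantile", "kmeans"), varFloor = 1e-6,
                     seed = 1L) {
  if (eps <= 0) stop("eps must be positive")
  if (maxIter < 1) stop("maxIter must be >= 1")
  if (K < 1) stop("K must be >= 1")
  structure(list(eps = eps, maxIter = as.integer(maxIter), K = as.integer(K),
                 init = match.arg(init), varFloor = varFloor,
                 seed = as.integer(seed)),
            class = "emConfig")
}

## Gaussian mixture log-density matrix: n x K of log(pi_k) + log N(x|mu_k, s2_k)
.logComponentDensity <- function(x, weights, means, variances) {
  K <- length(weights)
  out <- matrix(0, length(x), K)
  for (k in seq_len(K))
    out[, k] <- log(weights[k]) +
      stats::dnorm(x, means[k], sqrt(variances[k]), log = TRUE)
  out
}

.logSumExpRows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Fit a univariate Gaussian mixture by expectation-maximization
#'
#' Fits f(x) = sum_k pi_k N(x | mu_k, sigma_k^2) to one marker's log2
#' intensities. The E-step computes posterior responsibilities
#' gamma_ik = pi_k N(x_i|mu_k, sigma_k^2) / sum_j pi_j N(x_i|mu_j, sigma_j^2);
#' the M-step sets pi_k to the mean responsibility, mu_k to the
#' responsibility-weighted mean, and sigma_k^2 to the responsibility-weighted
#' variance about the updated mean. Iteration stops when the relative
#' log-likelihood change falls below \code{eps} or after \code{maxIter}
#' iterations. The log-likelihood is non-decreasing by construction and
#' asserted on every fit. Components whose weight collapses below 1e-6 are
#' pruned with a warning and the fit restarted with K-1 components.
#'
#' @param values numeric vector of log2 intensities (>= 2K distinct finite
#'   values required).
#' @param cfg an \code{\link{emConfig}}.
#' @return a \linkS4class{MixtureFit}.
#' @export
fitGmmEM <- function(values, cfg = emConfig()) {
  x <- values[is.finite(values)]
  n <- length(x)
  K <- cfg$K
  if (length(unique(x)) < 2L * K)
    stop("mixture fit error: need at least ", 2L * K,
         " distinct finite values, got ", length(unique(x)))
  if (K == 1L) {
    mu <- mean(x); s2 <- mean((x - mu)^2)  # MLE, not the n-1 variance
    ll <- sum(stats::dnorm(x, mu, sqrt(s2), log = TRUE))
    return(new("MixtureFit", K = 1L, weights = 1, means = mu, variances = s2,
               logLik = ll, nIter = 0L, converged = TRUE, n = n))
  }
  floor_s2 <- cfg$varFloor * stats::var(x)
  if (cfg$init == "quantile") {
    means <- as.numeric(stats::quantile(x, (2 * seq_len(K) - 1) / (2 * K),
                                        names = FALSE))
    variances <- rep(max(stats::var(x), floor_s2), K)
    weights <- rep(1 / K, K)
  } else {
    old <- .Random.seed_exists()
    set.seed(cfg$seed)
    km <- stats::kmeans(x, centers = K, nstart = 5)
    .restore_seed(old)
    ord <- order(km$centers)
    means <- as.numeric(km$centers[ord])
    weights <- as.numeric(table(factor(km$cluster, levels = ord)) / n)
    variances <- pmax(vapply(ord, function(k) {
      v <- stats::var(x[km$cluster == k]); if (is.na(v)) 0 else v
    }, numeric(1)), floor_s2)
  }
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$maxIter) {
    iter <- iter + 1L
    lw <- .logComponentDensity(x, weights, means, variances)
    lse <- .logSumExpRows(lw)
    gamma <- exp(lw - lse)            # E-step responsibilities
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) < cfg$eps * (1 + abs(ll_prev))) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    nk <- colSums(gamma)
    if (any(nk / n < 1e-6)) {
      warning("degenerate mixture component pruned (weight < 1e-6); ",
              "refitting with K = ", K - 1L)
      cfg2 <- cfg; cfg2$K <- K - 1L
      return(fitGmmEM(x, cfg2))
    }
    weights <- nk / n                 # M-step
    means <- colSums(gamma * x) / nk
    variances <- pmax(colSums(gamma * (outer(x, means, "-")^2)) / nk,
                      floor_s2)
  }
  new("MixtureFit", K = K, weights = weights, means = means,
      variances = variances, logLik = ll_trace, nIter = iter,
      converged = converged, n = n)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Posterior component responsibilities under a fitted mixture
#'
#' @param values numeric vector.
#' @param fit a \linkS4class{MixtureFit}.
#' @return n x K matrix of posteriors; rows sum to 1.
#' @export
posteriorProbs <- function(values, fit) {
  lw <- .logComponentDensity(values, fit@weights, fit@means, fit@variances)
  exp(lw - .logSumExpRows(lw))
}

#' Call per-cell marker positivity from a fitted mixture
#'
#' A cell is positive when the component with the highest posterior
#' probability at its expression value is the component with the largest
#' mean ("highest side" of the histogram). An exact posterior tie is broken
#' toward negative.
#'
#' @param values numeric vector of (log2) expression values.
#' @param fit a \linkS4class{MixtureFit}.
#' @return logical vector of the same length.
#' @export
classifyPositive <- function(values, fit) {
  if (fit@K == 1L) return(rep(FALSE, length(values)))
  g <- posteriorProbs(values, fit)
  top <- which.max(fit@means)
  other_max <- apply(g[, -top, drop = FALSE], 1, max)
  out <- g[, top] > other_max            # tie (==) -> negative
  out[!is.finite(values)] <- NA
  out
}

#' Combine per-marker positivity calls by logical OR
#'
#' A cell is overall-positive if positive for at least one marker:
#' P_i = OR_b C_ib.
#'
#' @param calls logical matrix (cells x markers) or data.frame of equal
#'   length logical columns.
#' @return logical vector P.
#' @export
combineMarkersOr <- function(calls) {
  calls <- as.matrix(calls)
  if (!is.logical(calls)) {
    if (!all(calls %in% c(0, 1, NA)))
      stop("calls must be logical or 0/1")
    calls <- calls == 1
  }
  rowSums(calls, na.rm = TRUE) > 0
}

#' Label CE and N-CE cells from combined basal-marker positivity
#'
#' Epithelial cells positive for at least one basal marker (p63, CK5) are
#' labeled non-cancerous epithelial (N-CE); double-negative epithelial
#' cells are labeled cancerous epithelial (CE), reflecting the loss of the
#' basal layer in carcinoma. Stromal cells are labeled \code{"stroma"}.
#'
#' @param x a \linkS4class{CellTable}.
#' @param P logical overall-positivity vector of length \code{nCells(x)}.
#' @return the table with a \code{cell_type} column
#'   (\code{"CE"}, \code{"N-CE"}, \code{"stroma"}).
#' @export
labelCeNce <- function(x, P) {
  stopifnot(length(P) == nCells(x))
  df <- cellData(x)
  type <- ifelse(df$compartment == "epithelial",
                 ifelse(P, "N-CE", "CE"), "stroma")
  setCellColumn(x, "cell_type", type)
}

#' One-call cell classification for a core
#'
#' Fits one mixture per basal marker on the epithelial cells' log2
#' intensities, calls positivity, combines markers by OR, and labels
#' CE/N-CE/stroma.
#'
#' @param x a \linkS4class{CellTable}; intensities must be log2-transformed.
#' @param basalMarkers markers entering the OR (default p63 and CK5).
#' @param cfg an \code{\link{emConfig}}.
#' @param fits optional named list of prefitted \linkS4class{MixtureFit}
#'   objects per marker (e.g. fitted pooled across the cohort); markers
#'   without an entry are fitted on this core.
#' @return list with \code{table} (labeled \linkS4class{CellTable}),
#'   \code{fits} (named list of \linkS4class{MixtureFit}), and \code{calls}
#'   (logical cells x markers matrix; NA for non-epithelial cells).
#' @export
classifyCells <- function(x, basalMarkers = c("p63", "CK5"), cfg = emConfig(),
                          fits = NULL) {
  if (!logTransformed(x))
    stop("classifyCells expects log2-transformed intensities; ",
         "run normalizeLog2() first")
  missing_m <- setdiff(basalMarkers, markers(x))
  if (length(missing_m))
    stop("marker(s) not in table: ", paste(missing_m, collapse = ", "))
  epi <- cellData(x)$compartment == "epithelial"
  calls <- matrix(NA, nCells(x), length(basalMarkers),
                  dimnames = list(NULL, basalMarkers))
  used <- list()
  for (m in basalMarkers) {
    v <- intensities(x)[epi, m]
    used[[m]] <- if (!is.null(fits[[m]])) fits[[m]] else fitGmmEM(v, cfg)
    calls[epi, m] <- classifyPositive(v, used[[m]])
  }
  fits <- used
  P <- combineMarkersOr(calls[, , drop = FALSE] & !is.na(calls))
  list(table = labelCeNce(x, P), fits = fits, calls = calls)
}

#' Assign immune phenotypes from binary marker calls
#'
#' Composition rules: regulatory T cells (T_reg) are CD3+CD4+FOXP3+;
#' helper T cells (T_H) are CD3+CD4+ and, by default, FOXP3- so the two
#' classes are disjoint (set \code{thIncludesTreg = TRUE} for the
#' overlapping convention in which every T_reg also counts as T_H);
#' macrophages are CD68+. Cells matching none of the rules are
#' \code{"other"}.
#'
#' @param calls data.frame or logical matrix with columns \code{CD3},
#'   \code{CD4}, \code{CD8}, \code{CD68}, \code{FOXP3}.
#' @param thIncludesTreg use the overlapping T_H definition (CD3+CD4+)?
#' @return character vector: \code{"T_reg"}, \code{"T_H"},
#'   \code{"macrophage"}, or \code{"other"}. With the default disjoint
#'   convention each cell receives exactly one label; macrophage takes
#'   precedence over no T-cell label only (CD68+ on a T cell keeps the
#'   T-cell label).
#' @export
assignImmunePhenotypes <- function(calls, thIncludesTreg = FALSE) {
  calls <- as.data.frame(calls)
  need <- c("CD3", "CD4", "CD8", "CD68", "FOXP3")
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols))
    stop("immune call schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  cd3 <- as.logical(calls$CD3); cd4 <- as.logical(calls$CD4)
  cd68 <- as.logical(calls$CD68); foxp3 <- as.logical(calls$FOXP3)
  treg <- cd3 & cd4 & foxp3
  th <- if (thIncludesTreg) cd3 & cd4 else cd3 & cd4 & !foxp3
  out <- rep("other", nrow(calls))
  out[cd68] <- "macrophage"
  out[th] <- "T_H"
  out[treg] <- "T_reg"
  out
}
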