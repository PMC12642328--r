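#' @include AllClasses.R gmm.R
NULL

## Evaluate expr with a locally-set seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old))
  set.seed(seed)
  expr
}

#' Permutation chi-squared test for composition tables
#'
#' Tests association between a grade label and a category label at the
#' cell level. The observed statistic is the Pearson chi-squared of the
#' grade x category contingency table; the null distribution is obtained
#' by shuffling the grade labels over cells \code{nPerm} times (default
#' 10,000). The p-value uses the add-one correction
#' p = (1 + #\{perm >= obs\}) / (1 + nPerm), so it is never exactly zero.
#' Grades with zero cells are dropped with a warning. An optional
#' block-shuffle variant permutes whole cores to acknowledge within-core
#' correlation.
#'
#' @param grade,category per-cell label vectors of equal length.
#' @param nPerm number of label shuffles.
#' @param seed RNG seed (restored afterwards).
#' @param block optional per-cell block id (e.g. core id); when supplied,
#'   grade labels are shuffled between blocks, keeping cells of a block
#'   together.
#' @return list: \code{statistic} (observed Pearson chi-squared),
#'   \code{p.value}, \code{table} (observed contingency table),
#'   \code{nPerm}.
#' @export
permutationChisq <- function(grade, category, nPerm = 10000L, seed = 1L,
                             block = NULL) {
  keep <- !is.na(grade) & !is.na(category)
  grade <- if (is.factor(grade)) grade[keep] else factor(grade[keep])
  category <- factor(category[keep])
  empty <- levels(grade)[tabulate(grade, nbins = nlevels(grade)) == 0]
  if (length(empty)) {
    warning("dropping grade level(s) with zero cells: ",
            paste(empty, collapse = ", "))
    grade <- droplevels(grade)
  }
  if (nlevels(grade) < 2 || nlevels(droplevels(category)) < 2)
    stop("need at least 2 grades and 2 categories")
  stat <- function(g) {
    tab <- table(g, category)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  }
  obs <- stat(grade)
  perm <- .withSeed(seed, {
    if (is.null(block)) {
      vapply(seq_len(nPerm), function(i) stat(sample(grade)), numeric(1))
    } else {
      block <- factor(block[keep])
      bl_grade <- grade[match(levels(block), block)]   # one grade per block
      vapply(seq_len(nPerm), function(i) {
        stat(sample(bl_grade)[as.integer(block)])
      }, numeric(1))
    }
  })
  list(statistic = as.numeric(obs),
       p.value = (1 + sum(perm >= as.numeric(obs) - 1e-12)) / (1 + nPerm),
       table = table(grade, category), nPerm = nPerm)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment:
#' q_i = min_\{j >= rank(i)\} m p_(j) / j, capped at 1.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted q-values, in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-sided permutation test for a difference in medians
#'
#' Statistic |median(a) - median(b)|; the null is generated by permuting
#' the pooled group labels \code{nPerm} times. Ties with the observed
#' statistic count toward the tail, and the add-one correction is applied.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param nPerm number of permutations.
#' @param seed RNG seed (restored afterwards).
#' @return list: \code{statistic}, \code{p.value}, \code{nPerm}.
#' @export
permutationDiffTest <- function(a, b, nPerm = 10000L, seed = 1L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b))
    stop("test error: both groups must be non-empty")
  obs <- abs(stats::median(a) - stats::median(b))
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  perm <- .withSeed(seed, vapply(seq_len(nPerm), function(i) {
    idx <- sample.int(n, na)
    abs(stats::median(pool[idx]) - stats::median(pool[-idx]))
  }, numeric(1)))
  list(statistic = obs,
       p.value = (1 + sum(perm >= obs - 1e-12)) / (1 + nPerm),
       nPerm = nPerm)
}

#' Fold change of medians between CE and N-CE cells
#'
#' Ratio of group medians on the linear intensity scale, reported with its
#' log2. A value above 1 indicates higher expression in CE cells.
#'
#' @param ce,nce linear-scale intensity vectors.
#' @return list: \code{fold}, \code{log2_fold}; both \code{NA} when either
#'   median is nonpositive.
#' @export
logFoldChange <- function(ce, nce) {
  m1 <- stats::median(ce, na.rm = TRUE)
  m2 <- stats::median(nce, na.rm = TRUE)
  if (!isTRUE(m1 > 0) || !isTRUE(m2 > 0))
    return(list(fold = NA_real_, log2_fold = NA_real_))
  list(fold = m1 / m2, log2_fold = log2(m1 / m2))
}

#' Kruskal-Wallis rank test across grades
#'
#' Tie-corrected rank H statistic with a chi-squared reference on k - 1
#' degrees of freedom. All-identical values give H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 non-empty groups).
#' @return list: \code{statistic} (H), \code{p.value}, \code{df}.
#' @export
kruskalWallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p.value = 1, df = nlevels(groups) - 1L))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = as.numeric(kt$statistic), p.value = kt$p.value,
       df = as.integer(kt$parameter))
}

#' Dichotomize patient feature values at the cohort median
#'
#' Patients at or above the cohort median form the \code{"far"} group
#' (the >= convention used for the printed distance cutoffs); patients
#' below it the \code{"near"} group. Missing values are excluded.
#'
#' @param values named (or unnamed) numeric vector, one per patient.
#' @return list: \code{group} (factor near/far, NA for missing values),
#'   \code{cutoff} (the cohort median).
#' @export
dichotomizeByMedian <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("split error: need at least 2 finite values")
  med <- stats::median(values[ok])
  grp <- rep(NA_character_, length(values))
  grp[ok] <- ifelse(values[ok] >= med, "far", "near")
  list(group = factor(grp, levels = c("near", "far")), cutoff = med)
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per group and the log-rank statistic
#' (observed vs expected events at each event time with hypergeometric
#' variance), referred to chi-squared on 1 degree of freedom. Patients
#' without an event are treated as censored at their follow-up time; an
#' optional administrative-censoring horizon (e.g. 60 months for 5-year
#' recurrence) re-censors longer follow-up.
#'
#' @param time follow-up times (months).
#' @param event logical/0-1 event indicators.
#' @param group two-level group factor (both groups non-empty).
#' @param censorAt optional administrative censoring horizon (months).
#' @return list: \code{statistic} (log-rank chi-squared), \code{p.value},
#'   \code{fit} (a \code{survival::survfit} object), \code{n} per group.
#' @export
kmLogrank <- function(time, event, group, censorAt = NULL) {
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- as.logical(event[keep])
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) != 2 || any(tabulate(group) == 0))
    stop("test error: need two non-empty groups")
  if (!is.null(censorAt)) {
    event <- event & time <= censorAt
    time <- pmin(time, censorAt)
  }
  if (!any(event)) stop("test error: need at least one event")
  s <- survival::Surv(time, event)
  fit <- survival::survfit(s ~ group)
  sd <- survival::survdiff(s ~ group, rho = 0)
  chisq <- as.numeric(sd$chisq)
  list(statistic = chisq,
       p.value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       fit = fit, n = table(group))
}
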