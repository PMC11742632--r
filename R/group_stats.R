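# Group-level statistics: nonparametric two-group comparisons with Cohen's
# d, Benjamini-Hochberg FDR over regions, hemispheric asymmetry, a PCA-based
# disease-severity score, and the median-split high/low-BBBD contingency
# analysis.

.cohensD <- function(a, b) {
  nA <- length(a); nB <- length(b)
  sp2 <- ((nA - 1) * var(a) + (nB - 1) * var(b)) / (nA + nB - 2)
  if (!is.finite(sp2) || sp2 == 0) {
    if (mean(a) == mean(b)) return(0)
    return(sign(mean(a) - mean(b)) * Inf)
  }
  (mean(a) - mean(b)) / sqrt(sp2)
}

.cohensDPaired <- function(d) {
  if (all(d == 0)) return(0)
  s <- sd(d)
  if (s == 0) return(sign(mean(d)) * Inf)
  mean(d) / s
}

#' Two-group nonparametric comparison with effect size
#'
#' Mann-Whitney (exact when `nA*nB <= 400` and there are no ties, otherwise
#' normal approximation with tie/continuity correction), Kruskal-Wallis, or
#' paired Wilcoxon signed-rank, all two-sided, plus Cohen's d (pooled-SD
#' denominator with `nA + nB - 2` degrees of freedom; for paired data the
#' mean difference over its SD). A paired comparison of identical samples
#' returns statistic 0 and p = 1 by convention.
#'
#' @param a,b numeric samples (paired: equal length).
#' @param test `"mann_whitney"`, `"kruskal_wallis"` or `"wilcoxon_paired"`.
#' @return A [GroupComparison-class].
#' @export
compareGroups <- function(a, b,
                          test = c("mann_whitney", "kruskal_wallis",
                                   "wilcoxon_paired")) {
  test <- match.arg(test)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (test == "wilcoxon_paired") {
    if (length(a) != length(b)) {
      stop("paired comparison needs equal-length samples", call. = FALSE)
    }
    d <- a - b
    if (all(d == 0)) {
      return(new("GroupComparison", test = test, statistic = 0,
                 pValue = 1, pAdjusted = NA_real_, effectSizeD = 0,
                 groupSizes = c(length(a), length(b)),
                 method = "all differences zero"))
    }
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
    return(new("GroupComparison", test = test,
               statistic = unname(wt$statistic), pValue = wt$p.value,
               pAdjusted = NA_real_, effectSizeD = .cohensDPaired(d),
               groupSizes = c(length(a), length(b)), method = wt$method))
  }
  if (test == "kruskal_wallis") {
    kt <- kruskal.test(list(a, b))
    return(new("GroupComparison", test = test,
               statistic = unname(kt$statistic), pValue = kt$p.value,
               pAdjusted = NA_real_, effectSizeD = .cohensD(a, b),
               groupSizes = c(length(a), length(b)), method = kt$method))
  }
  exact <- length(a) * length(b) <= 400 &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  new("GroupComparison", test = test, statistic = unname(wt$statistic),
      pValue = wt$p.value, pAdjusted = NA_real_,
      effectSizeD = .cohensD(a, b),
      groupSizes = c(length(a), length(b)),
      method = if (exact) "exact" else "normal approximation, tie-corrected")
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up procedure at level `q`: with ordered p-values `p(1) <= ... <=
#' p(m)`, reject all hypotheses up to `k = max{ i : p(i) <= i q / m }`.
#' Adjusted p-values come from the cumulative-minimum backward pass
#' (identical to `p.adjust(method = "BH")`). Input order is preserved.
#'
#' @param p p-values in `[0, 1]` (`NA` allowed; excluded from `m`).
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` and logical `reject` in input order.
#' @export
bhFdr <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- p.adjust(p, method = "BH")
  ok <- !is.na(p)
  m <- sum(ok)
  reject <- rep(NA, length(p))
  if (m > 0) {
    o <- order(p[ok])
    ps <- p[ok][o]
    below <- which(ps <= seq_len(m) * q / m)
    k <- if (length(below)) max(below) else 0L
    rej <- logical(m)
    if (k > 0) rej[o[seq_len(k)]] <- TRUE
    reject[ok] <- rej
  }
  list(p_adjusted = adj, reject = reject)
}

#' Left-right hemispheric asymmetry of regional values
#'
#' Pairs homologous left/right regions by their base name (the region name
#' with a trailing `_L`/`_R` token removed; midline regions are excluded)
#' and compares left against right with a paired Wilcoxon signed-rank test
#' and a paired Cohen's d. Positive d means left > right.
#'
#' @param regionValues named numeric vector (names = region ids), e.g. a
#'   subject's or group-average per-region modified z.
#' @param atlas a [BrainAtlas-class] whose table assigns hemispheres.
#' @return A [GroupComparison-class] (groups: left, right homologues).
#' @export
hemisphericAsymmetry <- function(regionValues, atlas) {
  stopifnot(is(atlas, "BrainAtlas"))
  tab <- atlas@table
  tab$base <- sub("_[LR]$", "", tab$name)
  lat <- tab[tab$hemisphere %in% c("L", "R"), ]
  wide <- merge(lat[lat$hemisphere == "L", c("base", "region_id")],
                lat[lat$hemisphere == "R", c("base", "region_id")],
                by = "base", suffixes = c("_L", "_R"))
  if (nrow(wide) == 0L) {
    stop("atlas has no homologous left/right region pairs", call. = FALSE)
  }
  left <- regionValues[as.character(wide$region_id_L)]
  right <- regionValues[as.character(wide$region_id_R)]
  keep <- is.finite(left) & is.finite(right)
  if (!any(keep)) stop("no finite homologous pairs", call. = FALSE)
  compareGroups(unname(left[keep]), unname(right[keep]),
                test = "wilcoxon_paired")
}

#' PCA-based disease-severity score and its correlation with BBBD
#'
#' Principal components of the standardized (zero-mean, unit-variance)
#' subject-by-feature matrix — the intended features are seizure frequency,
#' number of medications and years with epilepsy — correlated with a BBBD
#' measure by rank (Spearman, default) or Pearson correlation. Constant
#' feature columns are dropped with a warning.
#'
#' @param features data.frame or matrix, subjects x features.
#' @param bbbdMeasure per-subject BBBD measure (e.g. percent brain volume
#'   with BBBD, or number of flagged regions).
#' @param corMethod `"spearman"` (default) or `"pearson"`.
#' @return List: `pc_scores` (subjects x PCs), `explained_variance`,
#'   `loadings`, `correlation` (data.frame with r and p per PC).
#' @export
severityPca <- function(features, bbbdMeasure,
                        corMethod = c("spearman", "pearson")) {
  corMethod <- match.arg(corMethod)
  X <- as.matrix(features)
  if (nrow(X) < 4L) stop("need at least 4 subjects", call. = FALSE)
  if (length(bbbdMeasure) != nrow(X)) {
    stop("bbbdMeasure must have one value per subject", call. = FALSE)
  }
  keep <- apply(X, 2L, function(col) sd(col) > 0)
  if (!all(keep)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) < 1L) stop("no non-constant features left", call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  nPC <- min(2L, ncol(pc$x))
  corTab <- do.call(rbind, lapply(seq_len(nPC), function(k) {
    ct <- suppressWarnings(cor.test(pc$x[, k], bbbdMeasure,
                                    method = corMethod))
    data.frame(pc = paste0("PC", k), r = unname(ct$estimate),
               p = ct$p.value)
  }))
  list(pc_scores = pc$x, explained_variance = ev, loadings = pc$rotation,
       correlation = corTab, method = corMethod)
}

#' Median split into high/low BBBD with per-covariate Fisher tests
#'
#' Subjects strictly above the median of the BBBD measure form the `high`
#' group; ties at the median go to `low` (deterministic and, with distinct
#' values and even n, reproduces balanced n/2 groups). Each binary covariate
#' is tested against the grouping with a two-sided Fisher exact test on the
#' 2x2 table.
#'
#' @param values per-subject BBBD measure (n >= 4).
#' @param covariates optional data.frame of per-subject covariates, each
#'   with exactly 2 levels (logical, factor or 2-valued vector).
#' @return List: `grouping` (factor high/low), `median`, `tests`
#'   (data.frame covariate/p, or NULL).
#' @export
medianSplit <- function(values, covariates = NULL) {
  if (length(values) < 4L) stop("need at least 4 subjects", call. = FALSE)
  med <- median(values)
  grouping <- factor(ifelse(values > med, "high", "low"),
                     levels = c("high", "low"))
  tests <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    tests <- do.call(rbind, lapply(names(covariates), function(nm) {
      cv <- covariates[[nm]]
      f <- factor(cv)
      if (nlevels(f) != 2L) {
        stop("covariate '", nm, "' must have exactly 2 levels", call. = FALSE)
      }
      tab <- table(grouping, f)
      data.frame(covariate = nm,
                 p = fisher.test(tab)$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(grouping = grouping, median = med, tests = tests)
}

#' Region-wise patients-vs-controls comparison report
#'
#' Mann-Whitney test per region on the supra-threshold percentages, BH-FDR
#' across regions, and Cohen's d; plus the whole-brain comparison.
#'
#' @param controlPct controls x regions matrix of regional percentages.
#' @param patientPct patients x regions matrix.
#' @param regionIds region ids (columns).
#' @param q FDR level (default 0.05).
#' @return data.frame: `region_id`, `statistic`, `p`, `p_adjusted`,
#'   `reject`, `d`.
#' @export
regionComparisonReport <- function(controlPct, patientPct, regionIds,
                                   q = 0.05) {
  stopifnot(ncol(controlPct) == ncol(patientPct),
            ncol(controlPct) == length(regionIds))
  rows <- lapply(seq_along(regionIds), function(j) {
    a <- patientPct[, j]; b <- controlPct[, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) {
      return(data.frame(region_id = regionIds[j], statistic = NA_real_,
                        p = NA_real_, d = NA_real_))
    }
    gc <- compareGroups(a, b, "mann_whitney")
    data.frame(region_id = regionIds[j], statistic = gc@statistic,
               p = gc@pValue, d = gc@effectSizeD)
  })
  rep <- do.call(rbind, rows)
  fdr <- bhFdr(rep$p, q)
  rep$p_adjusted <- fdr$p_adjusted
  rep$reject <- fdr$reject
  rep[, c("region_id", "statistic", "p", "p_adjusted", "reject", "d")]
}
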