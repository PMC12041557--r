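#' Cohen's d
#'
#' Standardized mean difference (mean(a) - mean(b)) / pooled SD, with the
#' pooled SD sqrt(((n_a-1)s_a^2 + (n_b-1)s_b^2) / (n_a + n_b - 2)).
#'
#' @param a,b numeric samples with >= 2 values each.
#' @return d (positive when a exceeds b).
#' @export
cohensD <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  na <- length(a); nb <- length(b)
  pooled <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (pooled == 0) stop("degenerate samples: pooled sd is zero")
  (mean(a) - mean(b)) / pooled
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact p by enumeration over rank assignments when the combined sample size
#' is at most 12 and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction. Midranks are used for ties.
#'
#' @param a,b numeric samples (>= 1 value each).
#' @param method "auto" (the rule above), "exact", or "approx".
#' @return list with \code{statistic} (Mann-Whitney U for sample a) and
#'   \code{p} (two-sided).
#' @export
wilcoxonRankSum <- function(a, b, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- switch(method,
    auto = !ties && length(a) + length(b) <= 12L,
    exact = TRUE,
    approx = FALSE)
  if (exact && ties)
    stop("exact enumeration is undefined with ties; use method = 'approx'")
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = unname(wt$p.value))
}

#' Leave-one-out sensitivity analysis of a two-predictor scan
#'
#' Quantifies each species' influence on the scan: for every species, the
#' tree and data are pruned to the remaining species and the scan is re-run
#' with the same predictors over the reference scan's family universe (the
#' family filters are frozen at the full-data stage, so effect sizes stay
#' comparable across drops). For the families significant in the reference
#' scan (first predictor's call), the refit effect sizes r are compared with
#' the full-data r values by Cohen's d and a Wilcoxon rank-sum test; species
#' whose removal shifts the r distribution (|d| above \code{dThreshold} or
#' BH-adjusted Wilcoxon q below \code{alpha}) are flagged influential.
#' Families degenerate after a removal (zero count variance) are excluded
#' pairwise from both vectors.
#'
#' @param fce the \linkS4class{FamilyCountExperiment} used for the reference
#'   scan (restricted to its family universe beforehand is fine; extra
#'   families are ignored).
#' @param reference the full-data two-predictor \linkS4class{ScanResult}.
#' @param alpha significance level for the influence flag (on BH-adjusted
#'   Wilcoxon p; default 0.05).
#' @param dThreshold |Cohen's d| above which a species is flagged (default
#'   0.2, a small effect).
#' @return a \linkS4class{LooResult}.
#' @export
looScan <- function(fce, reference, alpha = 0.05, dThreshold = 0.2) {
  stopifnot(is(reference, "ScanResult"))
  predictors <- reference@predictors
  fce <- .completeCaseSubset(fce, predictors)
  species <- colnames(fce)
  if (length(species) < 4L) stop("need >= 4 species for leave-one-out")
  focalPred <- predictors[1L]
  sig <- significantFamilies(reference, focalPred, "any")
  if (!length(sig)) stop("no significant reference families to track")
  sig <- intersect(sig, rownames(fce))
  refTab <- scanTable(reference)
  refTab <- refTab[refTab$predictor == focalPred, ]
  refR <- setNames(refTab$r, refTab$family_id)[sig]

  fceSig <- fce[sig, ]
  rows <- vector("list", length(species))
  rvals <- vector("list", length(species))
  for (i in seq_along(species)) {
    s <- species[i]
    sub <- .subsetSpecies(fceSig, setdiff(species, s))
    scan <- suppressWarnings(
      scanFamilies(sub, predictors, alpha = reference@alpha))
    tab <- scanTable(scan)
    tab <- tab[tab$predictor == focalPred, ]
    rloo <- setNames(tab$r, tab$family_id)
    common <- intersect(names(rloo), names(refR))
    d <- cohensD(rloo[common], refR[common])
    w <- wilcoxonRankSum(rloo[common], refR[common], method = "approx")
    rows[[i]] <- DataFrame(species_dropped = s,
                           n_families = length(common),
                           cohens_d = d, wilcoxon_p = w$p)
    rvals[[i]] <- rloo[common]
  }
  tab <- do.call(rbind, rows)
  tab$wilcoxon_q <- bhAdjust(tab$wilcoxon_p)
  tab$influential <- abs(tab$cohens_d) > dThreshold | tab$wilcoxon_q < alpha
  rownames(tab) <- NULL
  names(rvals) <- species
  new("LooResult", table = tab, rValues = rvals, referenceR = refR)
}

#' Compare expression measures between focal and background genes
#'
#' Wilcoxon rank-sum tests of each measure (e.g. FPKM-like expression level
#' and unique transcript count) between the focal genes and the background
#' (non-focal) genes, with direction summarized by the median difference
#' (focal minus background). Missing values are dropped per measure; a
#' measure missing for more than half the genes raises a warning.
#'
#' @param values data.frame with gene ids in the first column (or rownames)
#'   and one column per measure.
#' @param focalGenes character vector; background is disjoint by construction
#'   (genes not in the focal set).
#' @param backgroundGenes character vector of background genes; defaults to
#'   all non-focal genes in \code{values}.
#' @param measures measure column names (default: all numeric columns).
#' @return a data.frame: measure, n_focal, n_background, statistic, p,
#'   median_difference.
#' @export
compareExpression <- function(values, focalGenes, backgroundGenes = NULL,
                              measures = NULL) {
  if (!is.numeric(values[[1L]])) {
    rownames(values) <- values[[1L]]
    values[[1L]] <- NULL
  }
  if (is.null(backgroundGenes))
    backgroundGenes <- setdiff(rownames(values), focalGenes)
  if (length(intersect(focalGenes, backgroundGenes)))
    stop("focal and background gene sets must be disjoint")
  if (is.null(measures))
    measures <- names(values)[vapply(values, is.numeric, logical(1L))]
  out <- lapply(measures, function(m) {
    v <- values[[m]]
    names(v) <- rownames(values)
    if (mean(is.na(v)) > 0.5)
      warning("measure ", m, " missing for more than half the genes")
    fa <- v[intersect(focalGenes, rownames(values))]
    bg <- v[intersect(backgroundGenes, rownames(values))]
    fa <- fa[!is.na(fa)]; bg <- bg[!is.na(bg)]
    w <- wilcoxonRankSum(fa, bg)
    data.frame(measure = m, n_focal = length(fa), n_background = length(bg),
               statistic = w$statistic, p = w$p,
               median_difference = median(fa) - median(bg))
  })
  do.call(rbind, out)
}
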