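# Cholesky of the Brownian covariance, with a tiny diagonal jitter retry when
# V is numerically singular (e.g. zero-length terminal branches).
.cholV <- function(V) {
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) {
    warning("covariance not positive definite; adding 1e-10 jitter")
    L <- chol(V + diag(1e-10, nrow(V)))
  }
  L
}

# Vectorized GLS over many response columns sharing one design and covariance.
# Y: n x F matrix of responses; X: n x k design (with intercept); V: n x n.
# Returns per-response coefficient/se/t/p matrices plus fit-level scalars.
.glsCore <- function(Y, X, V) {
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("need more species than coefficients")
  L <- .cholV(V)                           # V = t(L) %*% L
  Ys <- backsolve(L, Y, transpose = TRUE)  # whitened response(s)
  Xs <- backsolve(L, X, transpose = TRUE)
  XtX <- crossprod(Xs)
  if (rcond(XtX) < 1e-12) stop("collinear design")
  XtXinv <- solve(XtX)
  B <- XtXinv %*% crossprod(Xs, Ys)        # k x F
  E <- Ys - Xs %*% B
  rss <- colSums(E^2)                      # e' V^-1 e per response
  df <- n - k
  # numerically perfect fits: zero residual variance, so a coefficient is
  # either exactly zero (t = 0, p = 1) or carries infinite evidence
  scale2 <- colSums(Ys^2) + .Machine$double.xmin
  exactFit <- rss <= 1e-24 * scale2
  rss[exactFit] <- 0
  s2 <- rss / df
  se <- sqrt(outer(diag(XtXinv), s2))      # k x F
  tt <- B / se
  if (any(exactFit)) {
    tolB <- outer(sqrt(diag(XtXinv)), 1e-8 * sqrt(scale2 / n))
    zeroB <- abs(B) <= tolB
    tt[, exactFit] <- sign(B[, exactFit]) * Inf
    tt[zeroB & rep(exactFit, each = k)] <- 0
  }
  pp <- 2 * pt(-abs(tt), df)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi) + logdetV + n * log(sigma2) + n)
  ll[sigma2 == 0] <- Inf
  list(coef = B, se = se, t = tt, p = pp, df = as.integer(df),
       sigma2 = sigma2, logLik = ll, n = as.integer(n))
}

#' Generalized least squares under a fixed covariance
#'
#' Fits y = X beta + e with e ~ N(0, sigma2 * V) by the closed form
#' beta = (X'V^-1X)^-1 X'V^-1 y. Standard errors use the unbiased residual
#' scale e'V^-1e/(n - k), so with V = I the fit reproduces textbook OLS t
#' tests exactly; sigma2 is reported at the maximum-likelihood scale
#' e'V^-1e/n, and the log-likelihood is the Gaussian GLS likelihood at the ML
#' estimates (the convention of ML fits in nlme).
#'
#' @param y numeric response vector.
#' @param X design matrix including the intercept column; rows aligned with y
#'   and V on the same species order.
#' @param V covariance matrix (e.g. from \code{\link{brownianCovariance}}).
#' @return a \linkS4class{GlsFit}.
#' @examples
#' V <- brownianCovariance(readNewick("((A:1,B:1):1,C:2);"))
#' fitGls(c(1, 2, 4), cbind(1, x = 0:2), V)
#' @export
fitGls <- function(y, X, V) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), nrow(V) == nrow(X))
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))
  core <- .glsCore(matrix(y, ncol = 1L), X, V)
  r <- effectSizeR(core$t[, 1L], core$df)
  new("GlsFit",
      coefficients = setNames(core$coef[, 1L], colnames(X)),
      se = setNames(core$se[, 1L], colnames(X)),
      t = setNames(core$t[, 1L], colnames(X)),
      p = setNames(core$p[, 1L], colnames(X)),
      r = setNames(r, colnames(X)),
      df = core$df, sigma2 = core$sigma2[1L], logLik = core$logLik[1L],
      n = core$n)
}

#' t-to-r effect size
#'
#' Converts a coefficient's t statistic into a correlation-scale effect size,
#' r = t / sqrt(t^2 + df) — the partial correlation between response and
#' predictor given the rest of the design. Monotone in t, sign-preserving,
#' bounded in (-1, 1).
#'
#' @param t t statistic(s).
#' @param df residual degrees of freedom (> 0).
#' @return r on the same shape as t.
#' @export
effectSizeR <- function(t, df) {
  stopifnot(df > 0)
  ifelse(is.infinite(t), sign(t), t / sqrt(t^2 + df))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of p_(j) * m / j, clipped
#' at 1 and mapped back to the input order (ties by stable sort).
#'
#' @param p vector of p-values in [0,1].
#' @return adjusted q-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

.callFamilies <- function(r, q, alpha) {
  out <- rep("none", length(r))
  out[r > 0 & q < alpha] <- "expanding"
  out[r < 0 & q < alpha] <- "contracting"
  out
}

# subset to a species set, keeping tree and columns in step (tree tip order)
.subsetSpecies <- function(fce, keep) {
  tree <- pruneTo(familyTree(fce), keep)
  ans <- fce[, tree$tip.label]
  ans@tree <- tree
  ans
}

# restrict an experiment to species with complete values for the predictors
.completeCaseSubset <- function(fce, predictors) {
  traits <- as.data.frame(colData(fce))
  miss <- setdiff(predictors, names(traits))
  if (length(miss))
    stop("predictor(s) not in trait table: ", paste(miss, collapse = ", "))
  ok <- rownames(traits)[stats::complete.cases(traits[, predictors, drop = FALSE])]
  if (length(ok) < ncol(fce)) {
    message("dropping ", ncol(fce) - length(ok),
            " species with missing predictor values")
    fce <- .subsetSpecies(fce, ok)
  }
  fce
}

#' Per-family PGLS scan
#'
#' Fits one PGLS per gene family: response = that family's count vector across
#' species (raw integer counts by default), design = intercept + the listed
#' trait columns, covariance = Brownian covariance of the tree pruned to the
#' species with complete predictor data. Raw p-values are BH-adjusted within
#' each predictor across all scanned families, and each family x predictor is
#' called expanding (r > 0, q < alpha), contracting (r < 0, q < alpha) or
#' none. Families with zero count variance over the fitted species are
#' skipped with a warning (the fit is undefined).
#'
#' @param fce a \linkS4class{FamilyCountExperiment} whose colData carries the
#'   predictor columns (e.g. \code{log10_mlsp}, \code{relative_brain_size}).
#' @param predictors character vector of colData column names, design order.
#' @param alpha BH q threshold for the calls (default 0.05).
#' @param logCounts if TRUE the response is log1p(counts) instead of raw
#'   counts (off by default; family sizes are modelled on their natural
#'   count scale).
#' @return a \linkS4class{ScanResult}.
#' @export
scanFamilies <- function(fce, predictors, alpha = 0.05, logCounts = FALSE) {
  stopifnot(is(fce, "FamilyCountExperiment"), length(predictors) >= 1L)
  fce <- .completeCaseSubset(fce, predictors)
  tree <- familyTree(fce)
  V <- brownianCovariance(tree)
  traits <- as.data.frame(colData(fce))
  X <- cbind("(Intercept)" = 1,
             as.matrix(traits[tree$tip.label, predictors, drop = FALSE]))
  Y <- t(assay(fce, "counts")[, tree$tip.label, drop = FALSE])
  storage.mode(Y) <- "double"
  if (logCounts) Y <- log1p(Y)
  keep <- apply(Y, 2L, var) > 0
  if (any(!keep))
    warning(sum(!keep), " families skipped (zero count variance)")
  Y <- Y[, keep, drop = FALSE]
  if (ncol(Y) == 0L) stop("no family with count variance to scan")
  core <- .glsCore(Y, X, V)
  fam <- colnames(Y)
  rows <- vector("list", length(predictors))
  for (i in seq_along(predictors)) {
    j <- i + 1L  # skip intercept row
    tt <- core$t[j, ]
    p <- core$p[j, ]
    q <- bhAdjust(p)
    r <- effectSizeR(tt, core$df)
    rows[[i]] <- DataFrame(
      family_id = fam, predictor = predictors[i],
      beta = core$coef[j, ], se = core$se[j, ], t = tt,
      df = core$df, p = p, q = q, r = r,
      call = .callFamilies(r, q, alpha))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$family_id, tab$predictor), ]
  rownames(tab) <- NULL
  new("ScanResult", table = tab, predictors = predictors,
      alpha = alpha, nSpecies = core$n)
}

#' Control regression on the total gene count
#'
#' Tests whether the per-species total number of genes (the column sums of the
#' family-count matrix) is associated with a trait — the check that a
#' trait-correlated genome-wide inflation of gene number, e.g. from relaxed
#' purifying selection in long-lived species, is not driving per-family
#' results.
#'
#' @param fce a \linkS4class{FamilyCountExperiment}.
#' @param predictor a single trait column name.
#' @param alpha unused here, kept for interface symmetry.
#' @return a \linkS4class{GlsFit} for the single-predictor model.
#' @export
totalCountRegression <- function(fce, predictor, alpha = 0.05) {
  stopifnot(length(predictor) == 1L)
  fce <- .completeCaseSubset(fce, predictor)
  tree <- familyTree(fce)
  V <- brownianCovariance(tree)
  traits <- as.data.frame(colData(fce))
  y <- colSums(assay(fce, "counts")[, tree$tip.label, drop = FALSE])
  X <- cbind("(Intercept)" = 1,
             as.matrix(traits[tree$tip.label, predictor, drop = FALSE]))
  fitGls(y, X, V)
}

#' Write a scan table as TSV
#'
#' One row per family x predictor with columns family_id, predictor, beta,
#' se, t, df, p, q, r, call, in deterministic (family_id, predictor) order.
#'
#' @param scan a \linkS4class{ScanResult}.
#' @param file output path.
#' @export
writeScanTsv <- function(scan, file) {
  write.table(as.data.frame(scanTable(scan)), file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}
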