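test_that("GLS with identity covariance reproduces ordinary least squares", {
  set.seed(3)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    X <- cbind(1, matrix(rnorm(n * 2), n))
    colnames(X) <- c("(Intercept)", "x1", "x2")
    y <- rnorm(n)
    fit <- fitGls(y, X, diag(n))
    ols <- summary(lm(y ~ X[, 2] + X[, 3]))$coefficients
    expect_equal(unname(fit@coefficients), unname(ols[, 1]), tolerance = 1e-8)
    expect_equal(unname(fit@se), unname(ols[, 2]), tolerance = 1e-8)
    expect_equal(unname(fit@t), unname(ols[, 3]), tolerance = 1e-8)
    expect_equal(unname(fit@p), unname(ols[, 4]), tolerance = 1e-8)
  }
})

test_that("GLS matches the closed-form matrix expression on the 3-taxon tree", {
  V <- toyCov()
  y <- c(1, 2, 4)
  X <- cbind(1, x = 0:2)
  fit <- fitGls(y, X, V)
  oracle <- bruteForceGls(y, X, V)
  expect_equal(unname(fit@coefficients), unname(oracle$beta), tolerance = 1e-10)
  expect_equal(unname(fit@se), unname(oracle$se), tolerance = 1e-10)
  expect_equal(unname(fit@t), unname(oracle$t), tolerance = 1e-10)
  expect_equal(unname(fit@p), unname(oracle$p), tolerance = 1e-10)
})

test_that("GLS agrees with nlme's Brownian PGLS including the ML log-likelihood", {
  skip_if_not_installed("nlme")
  tr <- randomTree(10, seed = 17)
  set.seed(18)
  d <- data.frame(x = rnorm(10), sp = tr$tip.label)
  d$y <- 2 + 0.5 * d$x + rnorm(10)
  V <- brownianCovariance(tr)
  fit <- fitGls(d$y, cbind(1, x = d$x), V)
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(1, tr, form = ~sp),
                   method = "ML")
  tt <- summary(ref)$tTable
  expect_equal(unname(fit@coefficients), unname(tt[, "Value"]), tolerance = 1e-6)
  expect_equal(unname(fit@se), unname(tt[, "Std.Error"]), tolerance = 1e-6)
  expect_equal(unname(fit@p), unname(tt[, "p-value"]), tolerance = 1e-6)
  expect_equal(fit@logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("degenerate and equivariance properties of the GLS fit", {
  V <- toyCov()
  # constant response: zero slope, t = 0, p = 1
  fit <- fitGls(c(3, 3, 3), cbind(1, x = 0:2), V)
  expect_equal(unname(fit@coefficients[2]), 0)
  expect_equal(unname(fit@t[2]), 0)
  expect_equal(unname(fit@p[2]), 1)

  # scaling y scales beta and se, leaves t, p, r unchanged
  set.seed(5)
  y <- rnorm(3, 5)
  f1 <- fitGls(y, cbind(1, x = 0:2), V)
  f2 <- fitGls(7 * y, cbind(1, x = 0:2), V)
  expect_equal(f2@coefficients, 7 * f1@coefficients)
  expect_equal(f2@se, 7 * f1@se)
  expect_equal(f2@t, f1@t)
  expect_equal(f2@p, f1@p)
  expect_equal(f2@r, f1@r)

  # collinear design rejected
  expect_error(fitGls(y, cbind(1, x = c(1, 1, 1)), V), "collinear")
})

test_that("effect size r is the t-to-partial-correlation conversion", {
  expect_equal(effectSizeR(0, 10), 0)
  expect_equal(effectSizeR(2, 4), 2 / sqrt(8))
  ts <- seq(0, 50, by = 0.5)
  rs <- effectSizeR(ts, 7)
  expect_true(all(diff(rs) > 0))         # monotone
  expect_true(all(rs >= 0 & rs < 1))     # bounded, -> 1 in the limit
  expect_gt(effectSizeR(1e8, 7), 1 - 1e-10)
  expect_equal(effectSizeR(-3, 5), -effectSizeR(3, 5))
})

test_that("BH adjustment reproduces the hand-computed step-up and its properties", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(rep(0.05, 4)), rep(0.05, 4))
  expect_equal(bhAdjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_error(bhAdjust(c(0.5, 1.2)), "0,1|\\[0,1\\]")

  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    q <- bhAdjust(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))   # monotone in p
    # thresholding q reproduces the BH step-up rejection set at any level
    for (alpha in c(0.01, 0.05, 0.2)) {
      m <- length(p)
      ps <- sort(p)
      kmax <- suppressWarnings(max(which(ps <= alpha * seq_len(m) / m)))
      stepUp <- if (is.finite(kmax)) p <= ps[kmax] else rep(FALSE, m)
      expect_identical(q <= alpha, stepUp)
    }
  }
})

test_that("scanFamilies fits, adjusts and calls families", {
  st <- starTree(8)
  x <- setNames(seq(0, 7), st$tip.label)
  perfect <- matrix(rep(5 + 3 * x, each = 2), 2, 8, byrow = FALSE,
                    dimnames = list(c("f1", "f2"), st$tip.label))
  perfect <- rbind(perfect, f3 = rep(4, 8))   # zero-variance family
  traits <- data.frame(row.names = st$tip.label, pred = x)
  fce <- FamilyCountExperiment(perfect, traits, st)
  expect_warning(sc <- scanFamilies(fce, "pred"), "zero count variance")
  tab <- scanTable(sc)
  expect_setequal(tab$family_id, c("f1", "f2"))
  expect_true(all(tab$p < 1e-12))
  expect_true(all(tab$call == "expanding"))
  expect_true(all(tab$q >= tab$p))
})

test_that("scan calls partition the scanned families", {
  d <- simulatedScanData(nSpecies = 25, nFamilies = 300, seed = 31)
  sc <- suppressWarnings(scanFamilies(d$fce, "log10_mlsp"))
  tab <- scanTable(sc)
  expect_equal(sum(tab$call == "expanding") + sum(tab$call == "contracting") +
                 sum(tab$call == "none"), nrow(tab))
  # q is monotone in p within the predictor
  ord <- order(tab$p)
  expect_true(all(diff(tab$q[ord]) >= -1e-15))
  # deterministic row order: family then predictor
  expect_identical(tab$family_id, sort(tab$family_id))
})

test_that("a pure-noise second predictor preserves planted-effect recovery", {
  d <- simulatedScanData(nSpecies = 40, nFamilies = 600,
                         fracAssociated = 0.15, seed = 41)
  s1 <- suppressWarnings(scanFamilies(d$fce, "log10_mlsp"))
  noise <- as.data.frame(colData(d$fce))
  set.seed(42)
  # pure noise relative to the planted predictor: orthogonalized draw, so the
  # comparison is not confounded by chance collinearity with the Brownian trait
  raw <- rnorm(nrow(noise))
  X <- cbind(1, noise$log10_mlsp)
  Vi <- solve(brownianCovariance(familyTree(d$fce)))
  noise$junk <- drop(raw - X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% raw))
  fce2 <- FamilyCountExperiment(assay(d$fce, "counts"), noise, familyTree(d$fce))
  s2 <- suppressWarnings(scanFamilies(fce2, c("log10_mlsp", "junk")))
  assoc <- d$truth$family_id[d$truth$associated]
  pow1 <- mean(assoc %in% significantFamilies(s1, "log10_mlsp", "expanding"))
  pow2 <- mean(assoc %in% significantFamilies(s2, "log10_mlsp", "expanding"))
  expect_lt(abs(pow1 - pow2), 0.15)  # within Monte-Carlo error
})

test_that("total-count control regression behaves on constructed totals", {
  st <- starTree(10)
  set.seed(43)
  x <- setNames(rnorm(10), st$tip.label)
  traits <- data.frame(row.names = st$tip.label, pred = x)

  # identical species totals -> t = 0, p = 1
  m <- matrix(3, 5, 10, dimnames = list(sprintf("f%d", 1:5), st$tip.label))
  m[1, ] <- m[1, ] + rep(c(0, 1), 5)  # keep some per-family variance
  m[2, ] <- m[2, ] - rep(c(0, 1), 5)  # totals still constant
  fce <- FamilyCountExperiment(m, traits, st)
  fit <- totalCountRegression(fce, "pred")
  expect_equal(unname(fit@t[2]), 0)
  expect_equal(unname(fit@p[2]), 1)

  # totals exactly linear in the trait (V proportional to I) -> exact slope
  m2 <- matrix(0, 2, 10, dimnames = list(c("f1", "f2"), st$tip.label))
  m2[1, ] <- 10 + 2 * x
  m2[2, ] <- 5 + 1 * x
  fce2 <- FamilyCountExperiment(round(m2, 10), traits, st)
  fit2 <- totalCountRegression(fce2, "pred")
  expect_equal(unname(fit2@coefficients[2]), 3, tolerance = 1e-10)
})
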