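# shared fixture builders; everything is generated in code, nothing on disk

# the 3-taxon tree whose Brownian covariance is [[2,1,0],[1,2,0],[0,0,2]]
toyTree <- function() readNewick("((A:1,B:1):1,C:2);")

toyCov <- function() {
  V <- matrix(c(2, 1, 0, 1, 2, 0, 0, 0, 2), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  V
}

# random ultrametric tree via the package generator (unit height)
randomTree <- function(n, seed) simulateTree(n, seed = seed)

# star tree: n tips all attached to the root at depth `depth`
starTree <- function(n, depth = 1) {
  labs <- sprintf("t%02d", seq_len(n))
  readNewick(paste0("(", paste0(labs, ":", depth, collapse = ","), ");"))
}

# small simulated dataset ready for scanning
simulatedScanData <- function(nSpecies = 30, nFamilies = 400,
                              fracAssociated = 0.1, seed = 1,
                              targetEffectR = 0.6) {
  tree <- simulateTree(nSpecies, seed = seed)
  trt <- simulateTraits(tree, seed = seed + 1)
  x <- setNames(log10(trt$traits$mlsp), rownames(trt$traits))
  fam <- simulateFamilyCounts(tree, x, nFamilies = nFamilies,
                              fracAssociated = fracAssociated,
                              targetEffectR = targetEffectR, seed = seed + 2)
  traits <- relativeBrainSize(log10Traits(trt$traits))
  fce <- FamilyCountExperiment(fam$counts, traits, tree)
  list(tree = tree, x = x, traits = traits, fce = fce, truth = fam$truth)
}

# brute-force GLS coefficients by the explicit matrix expression
bruteForceGls <- function(y, X, V) {
  Vi <- solve(V)
  bhat <- solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
  e <- y - X %*% bhat
  df <- length(y) - ncol(X)
  s2 <- drop(t(e) %*% Vi %*% e) / df
  se <- sqrt(s2 * diag(solve(t(X) %*% Vi %*% X)))
  tt <- drop(bhat) / se
  list(beta = drop(bhat), se = se, t = tt, p = 2 * pt(-abs(tt), df))
}
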