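test_that("simulated trees are ultrametric, unit height and reproducible", {
  two <- simulateTree(2, seed = 1)
  expect_equal(sort(two$tip.label), c("s01", "s02"))
  expect_equal(unname(ape::node.depth.edgelength(two)[1:2]), c(1, 1))

  tr <- simulateTree(46, seed = 3)
  expect_equal(ape::Ntip(tr), 46L)
  depths <- ape::node.depth.edgelength(tr)[1:46]
  expect_lt(max(abs(depths - 1)), 1e-12)

  expect_identical(writeNewick(simulateTree(20, seed = 9)),
                   writeNewick(simulateTree(20, seed = 9)))
  expect_false(identical(writeNewick(simulateTree(20, seed = 9)),
                         writeNewick(simulateTree(20, seed = 10))))
})

test_that("simulated traits carry the requested Brownian structure", {
  tr <- simulateTree(20, seed = 4)
  # rate 0: no evolution, all species share the root state
  flat <- simulateTraits(tr, brownianRate = 0, seed = 5)
  expect_equal(var(flat$traits$mlsp), 0)

  # non-PSD correlation matrix rejected
  bad <- matrix(c(1, 2, 2, 1), 2, dimnames = rep(list(c("mlsp", "body_mass")), 2))
  expect_error(simulateTraits(tr, traitCorrelations = bad), "positive semi-definite")

  # independent traits: mean PIC correlation near zero
  tr46 <- simulateTree(46, seed = 6)
  R <- diag(2); dimnames(R) <- rep(list(c("mlsp", "body_mass")), 2)
  rs <- vapply(1:300, function(i) {
    lat <- simulateTraits(tr46, traitCorrelations = R, seed = 700 + i)$latent
    picCorrelation(tr46, lat[, 1], lat[, 2])$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.05)

  # raw traits are positive and the allometric residual is recoverable
  full <- simulateTraits(tr, seed = 8)
  expect_true(all(unlist(full$traits) > 0))
  # the OLS allometric residual is contaminated by phylogenetically
  # structured slope error, so recovery is strong but not perfect
  rec <- relativeBrainSize(log10Traits(full$traits))$relative_brain_size
  expect_gt(cor(rec, full$latent[, "brain_resid"]), 0.5)
})

test_that("family counts interlock with the filters and warn on clipping", {
  tr <- simulateTree(10, seed = 11)
  x <- setNames(rnorm(10), tr$tip.label)
  # no slope, no noise: every family constant, all removed by the cascade
  flat <- simulateFamilyCounts(tr, x, nFamilies = 20, fracAssociated = 0,
                               noiseSd = 0, seed = 12)
  expect_equal(nrow(suppressMessages(filterFamilies(flat$counts))), 0L)

  # baseline too small relative to noise: clip warning
  expect_warning(
    simulateFamilyCounts(tr, x, nFamilies = 50, countBaseline = 1,
                         noiseSd = 3, seed = 13),
    "clipped")

  # determinism and ground-truth bookkeeping
  a <- simulateFamilyCounts(tr, x, nFamilies = 100, seed = 14)
  b <- simulateFamilyCounts(tr, x, nFamilies = 100, seed = 14)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_equal(sum(a$truth$associated), round(0.05 * 100))
  expect_true(all(a$truth$true_b[!a$truth$associated] == 0))
  expect_true(all(a$truth$true_b[a$truth$associated] > 0))

  pois <- simulateFamilyCounts(tr, x, nFamilies = 50, seed = 15,
                               family = "poisson")
  expect_true(all(pois$counts == round(pois$counts)))
})

test_that("annotation simulation plants terms only when odds exceed one", {
  mem <- simulateMembership(sprintf("F%03d", 1:200), seed = 16)
  expect_false(anyDuplicated(mem$gene_id) > 0)
  expect_true(all(table(mem$family_id) >= 1))

  assoc <- sprintf("F%03d", 1:40)
  ann <- simulateAnnotations(mem, assoc, nTerms = 30, plantedTerms = 3,
                             enrichmentOdds = 8, seed = 17)
  expect_length(ann$planted, 3L)
  # planted terms are denser on associated families
  inc <- vapply(ann$planted, function(tm) {
    hit <- elementsWithTerm(ann$familyTerms, tm)
    mean(assoc %in% hit) - mean(setdiff(sprintf("F%03d", 1:200), assoc) %in% hit)
  }, numeric(1))
  expect_true(all(inc > 0.2))

  # genes inherit family terms: lifting the gene map recovers the family map
  lifted <- liftGoToFamilies(ann$geneTerms,
                             setNames(mem$family_id, mem$gene_id))
  for (f in names(ann$familyTerms@map))
    expect_setequal(as.character(lifted@map[[f]]),
                    as.character(ann$familyTerms@map[[f]]))

  empty <- simulateAnnotations(mem, assoc, nTerms = 0, seed = 18)
  expect_length(empty$geneTerms@map, 0L)
})

test_that("gene lists and expression tables carry their planted structure", {
  genes <- sprintf("g%04d", 1:2000)
  focal <- genes[1:400]
  lists <- simulateGeneLists(genes, focal, nLists = 2, overlapOdds = 6,
                             seed = 19)
  for (gl in lists) {
    fracFocal <- mean(focal %in% gl)
    fracOther <- mean(setdiff(genes, focal) %in% gl)
    expect_gt(fracFocal, fracOther)
    expect_identical(attr(gl, "background"), genes)
  }

  ex <- simulateExpression(genes, focal, shift = 2, seed = 20)
  expect_identical(ex, simulateExpression(genes, focal, shift = 2, seed = 20))
  cmp <- compareExpression(ex, focal)
  expect_true(all(cmp$p < 0.001))
  expect_true(all(cmp$median_difference > 0))

  nullEx <- simulateExpression(genes, focal, shift = 0, seed = 21)
  cmp0 <- compareExpression(nullEx, focal)
  expect_true(all(cmp0$p > 0.001))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulateTree(10, seed = 99))
  invisible(simulateTraits(simulateTree(5, seed = 1), seed = 98))
  expect_identical(.Random.seed, before)
})
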