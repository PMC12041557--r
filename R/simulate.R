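# run expr with a private RNG state seeded by `seed`, restoring the caller's
# stream afterwards, so generators are pure functions of (arguments, seed)
.withSeed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate an ultrametric species tree
#'
#' Pure-birth (Yule) tree on \code{nSpecies} tips, rescaled to unit
#' root-to-tip height — a stand-in with the statistical shape of a dated
#' mammalian phylogeny. Tips are labelled s01, s02, ... in tree order.
#'
#' @param nSpecies number of tips (>= 2); default 46.
#' @param seed integer RNG seed.
#' @return an ultrametric \code{phylo} of unit height.
#' @export
simulateTree <- function(nSpecies = 46L, seed = 1L) {
  stopifnot(nSpecies >= 2L)
  .withSeed(seed, {
    tr <- rphylo(nSpecies, birth = 1, death = 0)
    tr$edge.length <- tr$edge.length / max(node.depth.edgelength(tr))
    tr$tip.label <- sprintf("s%02d", seq_len(nSpecies))
    tr
  })
}

# default correlations of each simulated trait with MLSP (single common
# factor, so the implied trait correlation matrix is PSD by construction)
.defaultLoadings <- c(mlsp = 1, body_mass = 0.6, brain_resid = 0.7,
                      gestation_time = 0.7, age_sexual_maturity = 0.8)

#' Simulate correlated life-history traits on a tree
#'
#' Draws the latent trait matrix from a multivariate Brownian motion: each
#' column is Brownian on the tree and the cross-trait correlation matrix is
#' either supplied or built from single-factor loadings (each trait's
#' correlation with MLSP; this guarantees positive semi-definiteness and
#' matches the observed trait-MLSP correlation structure: body mass 0.6,
#' relative brain size 0.7, gestation time 0.7, age at sexual maturity 0.8).
#' Latent values are mapped to positive raw units (MLSP in years spanning
#' roughly 1-200, masses in grams, times in days) for I/O realism; the
#' mapping is monotone log-linear so it carries no inferential weight.
#'
#' @param tree a \code{phylo}.
#' @param traitCorrelations full correlation matrix over the simulated latent
#'   traits, or NULL to use the default factor loadings.
#' @param brownianRate variance accumulated per unit branch length (default 1).
#' @param seed integer RNG seed.
#' @return list with \code{traits} (data.frame of raw trait values, species as
#'   rownames) and \code{latent} (the standardized latent matrix).
#' @export
simulateTraits <- function(tree, traitCorrelations = NULL, brownianRate = 1,
                           seed = 1L) {
  nms <- names(.defaultLoadings)
  if (is.null(traitCorrelations)) {
    a <- .defaultLoadings
    R <- outer(a, a)
    diag(R) <- 1
  } else {
    R <- as.matrix(traitCorrelations)
    if (is.null(rownames(R))) dimnames(R) <- list(nms[seq_len(nrow(R))],
                                                  nms[seq_len(nrow(R))])
    nms <- rownames(R)
  }
  CR <- tryCatch(chol(R), error = function(e)
    stop("trait correlation matrix is not positive semi-definite"))
  V <- brownianCovariance(tree)
  LV <- .cholV(V)
  n <- Ntip(tree)
  Z <- .withSeed(seed, matrix(rnorm(n * nrow(R)), n, nrow(R)))
  lat <- crossprod(LV, Z) %*% CR * sqrt(brownianRate)  # N(0, rate * V (x) R)
  dimnames(lat) <- list(tree$tip.label, nms)
  traits <- data.frame(row.names = tree$tip.label)
  if ("mlsp" %in% nms) traits$mlsp <- 10^(1.2 + 0.55 * lat[, "mlsp"])
  if ("body_mass" %in% nms) traits$body_mass <- 10^(3.5 + 1.1 * lat[, "body_mass"])
  if (all(c("body_mass", "brain_resid") %in% nms))
    traits$brain_mass <- 10^(0.75 * log10(traits$body_mass) - 1.3 +
                               0.2 * lat[, "brain_resid"])
  if ("gestation_time" %in% nms)
    traits$gestation_time <- 10^(1.8 + 0.4 * lat[, "gestation_time"])
  if ("age_sexual_maturity" %in% nms)
    traits$age_sexual_maturity <- 10^(2.6 + 0.5 * lat[, "age_sexual_maturity"])
  list(traits = traits, latent = lat)
}

# slope giving a target effect size r for the trait coefficient of a
# single-predictor PGLS on design (1, x) with covariance sigma2 * V:
# the t statistic has noncentrality b / (sigma * sqrt([(X'V^-1X)^-1]_22)),
# and r = t/sqrt(t^2 + df), so set delta = r sqrt(df/(1-r^2)).
.slopeForTargetR <- function(x, V, targetR, sigma) {
  X <- cbind(1, x)
  L <- .cholV(V)
  Xs <- backsolve(L, X, transpose = TRUE)
  c22 <- solve(crossprod(Xs))[2L, 2L]
  df <- length(x) - 2L
  delta <- targetR * sqrt(df / (1 - targetR^2))
  delta * sigma * sqrt(c22)
}

#' Simulate a gene-family count matrix with planted trait associations
#'
#' Each family's latent size is baseline + b * x + u with u Brownian on the
#' tree (sd \code{noiseSd} per unit height). For a fraction
#' \code{fracAssociated} of families, b is calibrated so the expected PGLS
#' effect size of the trait coefficient equals \code{targetEffectR} (sign
#' drawn positive; the noncentrality of the slope t test is matched to the
#' target, see the methods vignette); otherwise b = 0. Counts are the latent
#' values rounded and clipped at zero, so the Gaussian PGLS model is
#' correctly specified up to rounding; \code{integerize = FALSE} returns the
#' latent Gaussian values and \code{family = "poisson"} draws Poisson counts
#' with the latent value as mean (a deliberate misspecification stress test).
#'
#' @param tree a \code{phylo}.
#' @param x named trait vector over the tips (the predictor, e.g. log10 MLSP).
#' @param nFamilies number of families (default 4000).
#' @param fracAssociated fraction with a planted association (default 0.05).
#' @param targetEffectR target effect size for associated families (default 0.6).
#' @param countBaseline mean genes per family (default 10).
#' @param noiseSd Brownian residual sd per unit height (default 3, so integer rounding is a negligible perturbation of the Gaussian model).
#' @param seed integer RNG seed.
#' @param integerize round and clip to integer counts (default TRUE).
#' @param family "gaussian" (default) or "poisson".
#' @param calibrationSpecies optional species subset on which the effect-size
#'   calibration is computed (when downstream analysis will drop species, the
#'   target applies to the retained set; Brownian marginals make the noise
#'   model consistent under subsetting).
#' @return list with \code{counts} (families x species matrix) and
#'   \code{truth} (data.frame: family_id, associated, true_b, target_r).
#' @export
simulateFamilyCounts <- function(tree, x, nFamilies = 4000L,
                                 fracAssociated = 0.05, targetEffectR = 0.6,
                                 countBaseline = 10, noiseSd = 3, seed = 1L,
                                 integerize = TRUE,
                                 family = c("gaussian", "poisson"),
                                 calibrationSpecies = NULL) {
  family <- match.arg(family)
  stopifnot(all(tree$tip.label %in% names(x)))
  x <- x[tree$tip.label]
  n <- Ntip(tree)
  V <- brownianCovariance(tree)
  calSpecies <- if (is.null(calibrationSpecies)) tree$tip.label
                else intersect(tree$tip.label, calibrationSpecies)
  xc <- x[calSpecies] - mean(x[calSpecies])
  b1 <- .slopeForTargetR(xc, V[calSpecies, calSpecies], targetEffectR, noiseSd)
  nAssoc <- round(fracAssociated * nFamilies)
  famIds <- sprintf("fam%05d", seq_len(nFamilies))
  .withSeed(seed, {
    assoc <- rep(FALSE, nFamilies)
    assoc[sample.int(nFamilies, nAssoc)] <- TRUE
    b <- ifelse(assoc, b1, 0)
    LV <- .cholV(V)
    U <- crossprod(LV, matrix(rnorm(n * nFamilies), n, nFamilies)) * noiseSd
    latent <- countBaseline + outer(x - mean(x), b) + U
    counts <- switch(family,
      gaussian = if (integerize) pmax(round(latent), 0) else latent,
      poisson = matrix(rpois(length(latent), pmax(latent, 0.01)),
                       n, nFamilies))
    if (integerize || family == "poisson") {
      clipped <- mean(latent < 0.5)
      if (clipped > 0.10)
        warning(sprintf(
          "baseline too small relative to noise: %.1f%% of counts clipped at zero",
          100 * clipped))
    }
    counts <- t(counts)
    dimnames(counts) <- list(famIds, tree$tip.label)
    list(counts = counts,
         truth = data.frame(family_id = famIds, associated = assoc,
                            true_b = b, target_r = ifelse(assoc, targetEffectR, 0)))
  })
}

#' Simulate gene-to-family membership
#'
#' Assigns each family 1 + Poisson(meanGenes - 1) member genes, labelled
#' <family>_g1, <family>_g2, ...
#'
#' @param familyIds character vector of family ids.
#' @param meanGenes mean genes per family (default 2.5, matching a background
#'   of ~4,000 families holding ~10,000 genes).
#' @param seed integer RNG seed.
#' @return data.frame (gene_id, family_id).
#' @export
simulateMembership <- function(familyIds, meanGenes = 2.5, seed = 1L) {
  .withSeed(seed, {
    k <- 1L + rpois(length(familyIds), max(meanGenes - 1, 0))
    data.frame(
      gene_id = unlist(lapply(seq_along(familyIds), function(i)
        paste0(familyIds[i], "_g", seq_len(k[i]))), use.names = FALSE),
      family_id = rep(familyIds, k))
  })
}

#' Simulate GO-style annotations with planted over-representation
#'
#' Terms are assigned at family level: every term annotates a family with
#' probability \code{baseProb}, except that planted terms annotate associated
#' families with odds multiplied by \code{enrichmentOdds}. Genes inherit
#' their family's terms, so lifting gene annotations back to families
#' round-trips. Term ids are GO:0000001 ... ; the planted ones are the first
#' \code{plantedTerms}.
#'
#' @param membership data.frame (gene_id, family_id).
#' @param associatedFamilies character vector of families carrying the signal.
#' @param nTerms total number of terms (default 60).
#' @param plantedTerms how many terms are planted (default 5).
#' @param baseProb baseline annotation probability (default 0.15).
#' @param enrichmentOdds odds multiplier on planted terms in associated
#'   families (>= 1; 1 means no signal).
#' @param seed integer RNG seed.
#' @return list with \code{geneTerms} and \code{familyTerms} (both
#'   \linkS4class{AnnotationMap}) and \code{planted} (term ids).
#' @export
simulateAnnotations <- function(membership, associatedFamilies,
                                nTerms = 60L, plantedTerms = 5L,
                                baseProb = 0.15, enrichmentOdds = 8,
                                seed = 1L) {
  stopifnot(enrichmentOdds >= 1)
  plantedTerms <- min(plantedTerms, nTerms)
  fams <- sort(unique(as.character(membership[[2L]])))
  if (nTerms == 0L) {
    empty <- AnnotationMap(data.frame(element = character(), term = character()),
                           background = fams)
    return(list(geneTerms = empty, familyTerms = empty, planted = character()))
  }
  terms <- sprintf("GO:%07d", seq_len(nTerms))
  planted <- terms[seq_len(plantedTerms)]
  oddsBase <- baseProb / (1 - baseProb)
  pPlanted <- (oddsBase * enrichmentOdds) / (1 + oddsBase * enrichmentOdds)
  .withSeed(seed, {
    pairs <- lapply(terms, function(tm) {
      p <- rep(baseProb, length(fams))
      if (tm %in% planted) p[fams %in% associatedFamilies] <- pPlanted
      fams[runif(length(fams)) < p]
    })
    famPairs <- data.frame(
      element = unlist(pairs, use.names = FALSE),
      term = rep(terms, lengths(pairs)))
    familyTerms <- AnnotationMap(famPairs, background = fams)
    geneFam <- setNames(as.character(membership[[2L]]),
                        as.character(membership[[1L]]))
    byFam <- split(names(geneFam), unname(geneFam))
    genePairs <- data.frame(
      element = unlist(byFam[famPairs$element], use.names = FALSE),
      term = rep(famPairs$term, lengths(byFam[famPairs$element])))
    geneTerms <- AnnotationMap(genePairs, background = names(geneFam))
    list(geneTerms = geneTerms, familyTerms = familyTerms, planted = planted)
  })
}

#' Simulate curated gene lists with planted overlap
#'
#' Each list includes focal genes with probability \code{baseProb *
#' overlapOdds / (1 + baseProb * (overlapOdds - 1))}-style odds scaling and
#' other genes with \code{baseProb}; odds of 1 gives a null list.
#'
#' @param genes the gene universe.
#' @param focalGenes genes the lists should preferentially overlap.
#' @param nLists number of lists (default 3).
#' @param overlapOdds odds multiplier for focal genes (default 4; 1 = null).
#' @param baseProb baseline inclusion probability (default 0.1).
#' @param seed integer RNG seed.
#' @return named list of character vectors, each with a "background"
#'   attribute equal to the full universe.
#' @export
simulateGeneLists <- function(genes, focalGenes, nLists = 3L, overlapOdds = 4,
                              baseProb = 0.1, seed = 1L) {
  oddsBase <- baseProb / (1 - baseProb)
  pFocal <- (oddsBase * overlapOdds) / (1 + oddsBase * overlapOdds)
  .withSeed(seed, {
    out <- lapply(seq_len(nLists), function(i) {
      p <- ifelse(genes %in% focalGenes, pFocal, baseProb)
      g <- genes[runif(length(genes)) < p]
      attr(g, "background") <- genes
      g
    })
    names(out) <- sprintf("genelist%02d", seq_len(nLists))
    out
  })
}

#' Simulate an expression / transcript-count table
#'
#' Log-normal expression levels (FPKM-like) and 1 + Poisson transcript counts
#' per gene; focal genes receive a multiplicative (1 + shift) factor on both
#' scales. shift = 0 is the null.
#'
#' @param genes gene universe.
#' @param focalGenes genes receiving the shift.
#' @param shift non-negative multiplicative excess (default 0).
#' @param seed integer RNG seed.
#' @return data.frame (gene_id, expression_level, transcript_count).
#' @export
simulateExpression <- function(genes, focalGenes, shift = 0, seed = 1L) {
  stopifnot(shift >= 0)
  mult <- ifelse(genes %in% focalGenes, 1 + shift, 1)
  .withSeed(seed, data.frame(
    gene_id = genes,
    expression_level = rlnorm(length(genes), meanlog = 2, sdlog = 1) * mult,
    transcript_count = 1L + rpois(length(genes), 4 * mult)))
}

#' Write a complete synthetic input bundle
#'
#' Generates tree, traits, completeness scores, family counts with planted
#' MLSP associations, gene membership, annotations, gene lists and an
#' expression table, and writes them as the plain-text inputs the pipeline
#' reads (tree.nwk, counts.tsv, traits.tsv, completeness.tsv,
#' membership.tsv, annotations.tsv, genelists/, expression.tsv, truth.json).
#' A configurable number of low-quality decoy species (completeness below
#' the 0.80 threshold) is appended so the completeness filter has work to do;
#' the effect-size calibration is computed on the retained species. An
#' optional outlier species has its counts shifted upward in associated
#' families (for sensitivity-analysis testing).
#'
#' @param dir output directory (created if needed).
#' @param nSpecies species retained after completeness filtering (default 46).
#' @param nLowQuality decoy species failing the filter (default 6).
#' @param nFamilies,fracAssociated,targetEffectR,countBaseline,noiseSd passed
#'   to \code{\link{simulateFamilyCounts}}.
#' @param nTerms,plantedTerms,enrichmentOdds passed to
#'   \code{\link{simulateAnnotations}}.
#' @param expressionShift multiplicative excess for focal genes' expression.
#' @param outlierSpecies NULL, or a retained species id whose counts are
#'   shifted +10 in associated families.
#' @param seed master integer seed; all stage seeds derive from it.
#' @return invisibly, a list with every simulated object and the truth record.
#' @export
simulateBundle <- function(dir, nSpecies = 46L, nLowQuality = 6L,
                           nFamilies = 4000L, fracAssociated = 0.05,
                           targetEffectR = 0.6, countBaseline = 10,
                           noiseSd = 3, nTerms = 60L, plantedTerms = 5L,
                           enrichmentOdds = 8, expressionShift = 1,
                           outlierSpecies = NULL, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nAll <- nSpecies + nLowQuality
  tree <- simulateTree(nAll, seed = seed)
  tr <- simulateTraits(tree, seed = seed + 1L)
  completeness <- .withSeed(seed + 2L, {
    sc <- setNames(runif(nAll, 0.81, 1.0), tree$tip.label)
    if (nLowQuality > 0L)
      sc[sample(names(sc), nLowQuality)] <- runif(nLowQuality, 0.5, 0.8)
    sc
  })
  retained <- names(completeness)[completeness > 0.80]
  x <- log10(tr$traits$mlsp)
  names(x) <- rownames(tr$traits)
  fam <- simulateFamilyCounts(tree, x, nFamilies = nFamilies,
                              fracAssociated = fracAssociated,
                              targetEffectR = targetEffectR,
                              countBaseline = countBaseline, noiseSd = noiseSd,
                              seed = seed + 3L,
                              calibrationSpecies = retained)
  counts <- fam$counts
  if (!is.null(outlierSpecies)) {
    stopifnot(outlierSpecies %in% colnames(counts))
    counts[fam$truth$associated, outlierSpecies] <-
      counts[fam$truth$associated, outlierSpecies] + 10L
  }
  membership <- simulateMembership(fam$truth$family_id, seed = seed + 4L)
  ann <- simulateAnnotations(membership,
                             fam$truth$family_id[fam$truth$associated],
                             nTerms = nTerms, plantedTerms = plantedTerms,
                             enrichmentOdds = enrichmentOdds, seed = seed + 5L)
  focalGenes <- membership$gene_id[
    membership$family_id %in% fam$truth$family_id[fam$truth$associated]]
  lists <- simulateGeneLists(membership$gene_id, focalGenes, seed = seed + 6L)
  expr <- simulateExpression(membership$gene_id, focalGenes,
                             shift = expressionShift, seed = seed + 7L)

  writeNewick(tree, file.path(dir, "tree.nwk"))
  .writeTsv(data.frame(family_id = rownames(counts), counts,
                       check.names = FALSE), file.path(dir, "counts.tsv"))
  .writeTsv(data.frame(species_id = rownames(tr$traits), tr$traits),
            file.path(dir, "traits.tsv"))
  .writeTsv(data.frame(species_id = names(completeness),
                       busco_completeness = completeness),
            file.path(dir, "completeness.tsv"))
  .writeTsv(membership, file.path(dir, "membership.tsv"))
  annPairs <- data.frame(
    element_id = rep(names(ann$geneTerms@map), lengths(ann$geneTerms@map)),
    term_id = unlist(ann$geneTerms@map, use.names = FALSE))
  .writeTsv(annPairs, file.path(dir, "annotations.tsv"))
  dir.create(file.path(dir, "genelists"), showWarnings = FALSE)
  for (nm in names(lists)) {
    writeLines(lists[[nm]], file.path(dir, "genelists", paste0(nm, ".txt")))
    writeLines(attr(lists[[nm]], "background"),
               file.path(dir, "genelists", paste0(nm, ".txt.background")))
  }
  .writeTsv(expr, file.path(dir, "expression.tsv"))
  truth <- list(
    seed = seed, n_species = nSpecies, n_low_quality = nLowQuality,
    retained_species = retained,
    associated_families = fam$truth$family_id[fam$truth$associated],
    target_effect_r = targetEffectR, planted_terms = ann$planted,
    focal_genes = focalGenes, outlier_species = outlierSpecies)
  write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
             digits = NA)
  invisible(list(tree = tree, traits = tr$traits, completeness = completeness,
                 counts = counts, truth = fam$truth, membership = membership,
                 annotations = ann, geneLists = lists, expression = expr,
                 retained = retained))
}

.writeTsv <- function(d, file) {
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
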