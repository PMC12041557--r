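setOldClass("phylo")

#' FamilyCountExperiment: gene family counts on a phylogeny
#'
#' The central data container: a \linkS4class{SummarizedExperiment} whose
#' single assay \code{"counts"} holds non-negative integer gene counts
#' (families in rows, species in columns), whose \code{colData} carries the
#' per-species trait table (raw and derived columns), and whose \code{tree}
#' slot holds the rooted, ultrametric species phylogeny (\code{ape::phylo})
#' from which the Brownian covariance is built. Tip labels of the tree match
#' the column names exactly (same set, tree tip order is authoritative).
#'
#' @slot tree an \code{ape::phylo} object, tips named as the columns.
#' @export
setClass("FamilyCountExperiment",
  contains = "SummarizedExperiment",
  slots = c(tree = "phylo")
)

setValidity("FamilyCountExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (any(m < 0, na.rm = TRUE)) msg <- c(msg, "counts must be non-negative")
  }
  tl <- object@tree$tip.label
  if (anyDuplicated(tl)) msg <- c(msg, "tree tip labels must be unique")
  if (!setequal(tl, colnames(object)))
    msg <- c(msg, "tree tips and species columns must be the same set")
  if (anyDuplicated(rownames(object))) msg <- c(msg, "family ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a FamilyCountExperiment
#'
#' Assembles counts, traits and tree into one object, restricting all three to
#' their common species set (species present in only some inputs are dropped
#' with a warning, mirroring per-analysis species intersections).
#'
#' @param counts integer matrix, families x species, with dimnames.
#' @param traits data.frame of per-species traits with rownames = species ids
#'   (or a \code{species_id} column).
#' @param tree rooted \code{ape::phylo} with branch lengths; tips = species.
#' @return a \linkS4class{FamilyCountExperiment} with columns in tree tip order.
#' @examples
#' tr <- readNewick("((A:1,B:1):1,C:2);")
#' cnt <- matrix(1:6, 2, 3, dimnames = list(c("f1", "f2"), c("A", "B", "C")))
#' td <- data.frame(row.names = c("A", "B", "C"), mlsp = c(10, 20, 40))
#' fce <- FamilyCountExperiment(cnt, td, tr)
#' @export
FamilyCountExperiment <- function(counts, traits, tree) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (!is.null(traits$species_id)) {
    rownames(traits) <- traits$species_id
    traits$species_id <- NULL
  }
  common <- Reduce(intersect, list(colnames(counts), rownames(traits), tree$tip.label))
  if (length(common) < 2L)
    stop("fewer than 2 species shared by counts, traits and tree")
  dropped <- setdiff(
    unique(c(colnames(counts), rownames(traits), tree$tip.label)), common)
  if (length(dropped))
    warning("dropping species absent from some inputs: ",
            paste(sort(dropped), collapse = ", "))
  tree <- pruneTo(tree, common)
  ord <- tree$tip.label
  se <- SummarizedExperiment(
    assays  = list(counts = counts[, ord, drop = FALSE]),
    colData = DataFrame(traits[ord, , drop = FALSE])
  )
  new("FamilyCountExperiment", se, tree = tree)
}

#' @describeIn FamilyCountExperiment accessor for the species phylogeny.
#' @param x a FamilyCountExperiment.
#' @export
familyTree <- function(x) {
  stopifnot(is(x, "FamilyCountExperiment"))
  x@tree
}

setMethod("show", "FamilyCountExperiment", function(object) {
  callNextMethod()
  cat("tree:", Ntip(object@tree), "tips, height",
      format(max(node.depth.edgelength(object@tree)), digits = 4), "\n")
})

#' GlsFit: a single generalized least squares fit
#'
#' Coefficients, standard errors (on the unbiased n - k scale), t statistics,
#' two-sided p-values, the t-derived effect sizes r, the ML Brownian rate
#' sigma2 and the Gaussian log-likelihood of one PGLS fit.
#'
#' @slot coefficients,se,t,p,r named numeric vectors, one entry per predictor
#'   column (including the intercept).
#' @slot df residual degrees of freedom (n - k).
#' @slot sigma2 maximum-likelihood residual rate e'V^-1 e / n.
#' @slot logLik Gaussian GLS log-likelihood at the ML estimates.
#' @slot n number of species fitted.
#' @export
setClass("GlsFit", representation(
  coefficients = "numeric", se = "numeric", t = "numeric", p = "numeric",
  r = "numeric", df = "integer", sigma2 = "numeric", logLik = "numeric",
  n = "integer"
))

setValidity("GlsFit", function(object) {
  if (object@df <= 0L) return("residual df must be positive")
  if (any(object@p < 0 | object@p > 1, na.rm = TRUE)) return("p outside [0,1]")
  TRUE
})

setMethod("show", "GlsFit", function(object) {
  cat("PGLS fit:", object@n, "species,", object@df, "residual df\n")
  print(data.frame(beta = object@coefficients, se = object@se, t = object@t,
                   p = object@p, r = object@r))
  cat("sigma2 (ML):", format(object@sigma2, digits = 5),
      " logLik:", format(object@logLik, digits = 6), "\n")
})

#' ScanResult: per-family PGLS scan summary
#'
#' One row per family x predictor: coefficient, standard error, t, residual
#' df, raw p, BH-adjusted q (adjusted within predictor across families),
#' effect size r, and the expansion/contraction call at level \code{alpha}.
#'
#' @slot table a \code{DataFrame} with columns family_id, predictor, beta, se,
#'   t, df, p, q, r, call.
#' @slot predictors scanned predictor names, in design order.
#' @slot alpha significance level used for the calls (BH q threshold).
#' @slot nSpecies number of species entering the fits.
#' @export
setClass("ScanResult", representation(
  table = "DataFrame", predictors = "character", alpha = "numeric",
  nSpecies = "integer"
))

setMethod("show", "ScanResult", function(object) {
  tab <- object@table
  cat("PGLS scan:", length(unique(tab$family_id)), "families x",
      length(object@predictors), "predictor(s),", object@nSpecies,
      "species, alpha =", object@alpha, "\n")
  for (pr in object@predictors) {
    cl <- tab$call[tab$predictor == pr]
    cat(sprintf("  %s: %d expanding, %d contracting, %d none\n", pr,
                sum(cl == "expanding"), sum(cl == "contracting"),
                sum(cl == "none")))
  }
})

#' @describeIn ScanResult the full per-family table.
#' @param x a ScanResult.
#' @export
scanTable <- function(x) {
  stopifnot(is(x, "ScanResult"))
  x@table
}

#' Families significantly called for a predictor
#'
#' @param x a \linkS4class{ScanResult}.
#' @param predictor predictor name (default: first scanned predictor).
#' @param direction "expanding", "contracting" or "any".
#' @return character vector of family ids.
#' @export
significantFamilies <- function(x, predictor = x@predictors[1L],
                                direction = c("any", "expanding", "contracting")) {
  direction <- match.arg(direction)
  tab <- scanTable(x)
  tab <- tab[tab$predictor == predictor, ]
  keep <- if (direction == "any") tab$call != "none" else tab$call == direction
  as.character(tab$family_id[keep])
}

#' AnnotationMap: opaque term annotations over a background
#'
#' Maps elements (gene ids or family ids) to sets of annotation terms (GO
#' terms treated as opaque labels; no graph propagation). The background is
#' the full element universe enrichment samples are drawn from; every
#' annotated element belongs to it.
#'
#' @slot map a \code{CharacterList}, names = element ids, values = term sets.
#' @slot background character vector of all background element ids.
#' @export
setClass("AnnotationMap", representation(
  map = "CharacterList", background = "character"
))

setValidity("AnnotationMap", function(object) {
  msg <- character()
  if (anyDuplicated(object@background)) msg <- c(msg, "background ids must be unique")
  if (!all(names(object@map) %in% object@background))
    msg <- c(msg, "every annotated element must be in the background")
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationMap
#'
#' @param pairs two-column data.frame (element_id, term_id); repeated rows are
#'   deduplicated.
#' @param background element universe; defaults to the annotated elements.
#' @param restrict if TRUE, annotations for elements outside the background
#'   are silently dropped (e.g. genes of families removed by the filter
#'   cascade); if FALSE (default) such elements are an error.
#' @return an \linkS4class{AnnotationMap}.
#' @export
AnnotationMap <- function(pairs, background = NULL, restrict = FALSE) {
  stopifnot(ncol(pairs) >= 2L)
  el <- as.character(pairs[[1L]]); tm <- as.character(pairs[[2L]])
  keep <- !duplicated(paste0(el, "\r", tm)) & nzchar(tm)
  if (restrict && !is.null(background)) keep <- keep & el %in% background
  el <- el[keep]; tm <- tm[keep]
  if (is.null(background)) background <- sort(unique(el))
  map <- CharacterList(split(tm, factor(el, levels = sort(unique(el)))))
  new("AnnotationMap", map = map, background = as.character(background))
}

setMethod("show", "AnnotationMap", function(object) {
  cat("AnnotationMap:", length(object@map), "annotated elements /",
      length(object@background), "background;",
      length(unique(unlist(object@map))), "terms\n")
})

#' @describeIn AnnotationMap terms present in the map.
#' @param x an AnnotationMap.
#' @export
termUniverse <- function(x) sort(unique(unlist(x@map, use.names = FALSE)))

#' @describeIn AnnotationMap elements annotated with a given term.
#' @param term a term id.
#' @export
elementsWithTerm <- function(x, term) {
  hit <- vapply(x@map, function(v) term %in% v, logical(1L))
  names(x@map)[hit]
}

#' EnrichmentResult: resampling Z-score enrichment summary
#'
#' @slot table per-term \code{DataFrame}: term, n_background,
#'   n_focal_observed, observed_proportion, null_mean, null_sd, z, p
#'   (two-sided normal tail), p_empirical, q (BH), direction, degenerate.
#' @slot nSamples number of resampled null sets.
#' @slot seed RNG seed used.
#' @export
setClass("EnrichmentResult", representation(
  table = "DataFrame", nSamples = "integer", seed = "integer"
))

setMethod("show", "EnrichmentResult", function(object) {
  cat("Resampling enrichment:", nrow(object@table), "terms,",
      object@nSamples, "null samples, seed", object@seed, "\n")
  cat(" ", sum(object@table$q < 0.05, na.rm = TRUE), "terms at q < 0.05\n")
})

#' @describeIn EnrichmentResult the per-term table.
#' @param x an EnrichmentResult.
#' @export
enrichmentTable <- function(x) x@table

#' LooResult: leave-one-out sensitivity summary
#'
#' @slot table per-species \code{DataFrame}: species_dropped, n_families,
#'   cohens_d, wilcoxon_p, wilcoxon_q, influential.
#' @slot rValues list of per-species effect-size vectors from the refits.
#' @slot referenceR the full-data effect sizes over the same families.
#' @export
setClass("LooResult", representation(
  table = "DataFrame", rValues = "list", referenceR = "numeric"
))

setMethod("show", "LooResult", function(object) {
  cat("Leave-one-out sensitivity:", nrow(object@table), "species,",
      length(object@referenceR), "reference families\n")
  infl <- object@table$species_dropped[object@table$influential]
  cat(" influential:", if (length(infl)) paste(infl, collapse = ", ") else "none", "\n")
})

#' @describeIn LooResult the per-species table.
#' @param x a LooResult.
#' @export
looTable <- function(x) x@table
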