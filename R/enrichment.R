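#' Read a two-column annotation TSV
#'
#' Columns element_id, term_id (header optional rows repeated allowed —
#' deduplicated on load).
#'
#' @param file path.
#' @param background optional element universe (defaults to annotated ids).
#' @param restrict drop annotations for elements outside the background.
#' @return an \linkS4class{AnnotationMap}.
#' @export
readAnnotationMap <- function(file, background = NULL, restrict = FALSE) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  AnnotationMap(d, background = background, restrict = restrict)
}

#' Read a gene list (one id per line), with optional paired background
#'
#' If \code{<file>.background} exists it is read as the list's own background
#' gene universe and attached as the \code{"background"} attribute.
#'
#' @param file path to the list.
#' @return character vector of gene ids, possibly with a background attribute.
#' @export
readGeneList <- function(file) {
  genes <- unique(trimws(readLines(file)))
  genes <- genes[nzchar(genes)]
  bg <- paste0(file, ".background")
  if (file.exists(bg)) {
    b <- unique(trimws(readLines(bg)))
    attr(genes, "background") <- b[nzchar(b)]
  }
  genes
}

#' Lift gene-level annotations to families
#'
#' A family inherits a term whenever that term is assigned to any of its
#' member genes (in any species): the family's term set is the union over its
#' genes. Genes annotated but absent from the membership map are skipped with
#' a warning. The resulting background is the family universe of the
#' membership map.
#'
#' @param geneTerms an \linkS4class{AnnotationMap} over genes.
#' @param membership data.frame (gene_id, family_id) or named character vector
#'   gene -> family.
#' @return an \linkS4class{AnnotationMap} over families.
#' @export
liftGoToFamilies <- function(geneTerms, membership) {
  if (is.data.frame(membership))
    membership <- setNames(as.character(membership[[2L]]),
                           as.character(membership[[1L]]))
  genes <- names(geneTerms@map)
  unknown <- setdiff(genes, names(membership))
  if (length(unknown)) {
    warning(length(unknown), " annotated gene(s) missing from membership map; skipped")
    genes <- setdiff(genes, unknown)
  }
  fams <- sort(unique(unname(membership)))
  if (!length(genes))
    return(new("AnnotationMap", map = CharacterList(structure(list(), names = character())),
               background = fams))
  pairs <- data.frame(
    element = rep(membership[genes], lengths(geneTerms@map[genes])),
    term = unlist(geneTerms@map[genes], use.names = FALSE)
  )
  AnnotationMap(pairs, background = fams)
}

#' Drop rarely annotated terms
#'
#' Keeps terms annotated to at least \code{minElements} background elements
#' (families or genes); terms below the threshold are removed from every
#' element's term set. Family-level enrichment conventionally uses 50,
#' gene-level 200.
#'
#' @param ann an \linkS4class{AnnotationMap}.
#' @param minElements minimum elements per retained term (>= 1).
#' @return the filtered \linkS4class{AnnotationMap}.
#' @export
filterTerms <- function(ann, minElements) {
  stopifnot(minElements >= 1L)
  counts <- table(unlist(ann@map, use.names = FALSE))
  keep <- names(counts)[counts >= minElements]
  map <- CharacterList(lapply(ann@map, function(v) v[v %in% keep]))
  map <- map[lengths(map) > 0L]
  new("AnnotationMap", map = map, background = ann@background)
}

# elements x terms logical incidence matrix over the background
.incidence <- function(ann) {
  terms <- termUniverse(ann)
  M <- matrix(FALSE, length(ann@background), length(terms),
              dimnames = list(ann@background, terms))
  if (length(ann@map)) {
    el <- rep(names(ann@map), lengths(ann@map))
    tm <- unlist(ann@map, use.names = FALSE)
    M[cbind(match(el, ann@background), match(tm, terms))] <- TRUE
  }
  M
}

#' Resampling Z-score enrichment
#'
#' For each term, the observed proportion of focal elements carrying the term
#' is compared against its null distribution over \code{nSamples} random
#' subsets of the background, each of the focal set's size, drawn uniformly
#' without replacement. z = (observed - null mean) / null sd; p is the
#' two-sided standard-normal tail; q is BH across terms. An empirical rank p
#' is reported alongside as a diagnostic. Terms whose null sd is zero are
#' flagged degenerate: p = 1 when the observation equals the null mean,
#' otherwise floored at 1/nSamples.
#'
#' @param focal character vector of focal element ids (subset of background).
#' @param ann an \linkS4class{AnnotationMap} (already term-filtered).
#' @param nSamples number of null samples (default 1000).
#' @param seed integer RNG seed; results are reproducible given it.
#' @param replace draw null samples with replacement (default FALSE: a random
#'   sample of the background is a subset).
#' @return an \linkS4class{EnrichmentResult}.
#' @export
samplingEnrichment <- function(focal, ann, nSamples = 1000L, seed = 1L,
                               replace = FALSE) {
  focal <- unique(as.character(focal))
  if (!length(focal)) stop("focal set is empty")
  if (!all(focal %in% ann@background))
    stop("focal elements outside the background: ",
         paste(head(setdiff(focal, ann@background), 5L), collapse = ", "))
  if (length(focal) > length(ann@background))
    stop("focal set larger than background")
  stopifnot(nSamples >= 2L)
  M <- .incidence(ann)
  nf <- length(focal)
  obs <- colMeans(M[focal, , drop = FALSE])

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nb <- nrow(M)
  nullProp <- matrix(0, nSamples, ncol(M))
  for (b in seq_len(nSamples)) {
    idx <- sample.int(nb, nf, replace = replace)
    nullProp[b, ] <- colMeans(M[idx, , drop = FALSE])
  }
  mu <- colMeans(nullProp)
  sdv <- apply(nullProp, 2L, sd)
  degenerate <- sdv == 0
  z <- ifelse(degenerate, NA_real_, (obs - mu) / sdv)
  p <- ifelse(degenerate,
              ifelse(obs == mu, 1, 1 / nSamples),
              2 * pnorm(-abs(z)))
  # empirical two-sided rank p (diagnostic)
  pemp <- vapply(seq_len(ncol(M)), function(j) {
    lo <- (sum(nullProp[, j] <= obs[j]) + 1) / (nSamples + 1)
    hi <- (sum(nullProp[, j] >= obs[j]) + 1) / (nSamples + 1)
    min(1, 2 * min(lo, hi))
  }, numeric(1L))
  tab <- DataFrame(
    term = colnames(M),
    n_background = unname(colSums(M)),
    n_focal_observed = unname(colSums(M[focal, , drop = FALSE])),
    observed_proportion = unname(obs),
    null_mean = unname(mu), null_sd = unname(sdv), z = unname(z),
    p = unname(p), p_empirical = pemp,
    q = unname(bhAdjust(p)),
    direction = unname(ifelse(obs >= mu, "over", "under")),
    degenerate = unname(degenerate))
  tab <- tab[order(tab$q, tab$p, tab$term), ]
  rownames(tab) <- NULL
  new("EnrichmentResult", table = tab, nSamples = as.integer(nSamples),
      seed = as.integer(seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Chi-square overlap of a curated gene list with the focal gene set
#'
#' Builds the 2x2 table of (in gene list) x (in focal set) over a harmonized
#' background — the study background intersected with the list's own
#' background when it has one — and applies Pearson's chi-square test without
#' continuity correction (df = 1). Direction is read off the in-list,
#' in-focal cell against its expectation, and log2_fold = log2(obs/exp) of
#' that cell. If any expected cell is below 1 the result is flagged
#' unreliable but still reported.
#'
#' @param geneList character vector of list genes.
#' @param listBackground the list's own background universe, or NULL.
#' @param focalGenes the study's focal genes (e.g. MLSP-associated genes),
#'   subset of studyBackground.
#' @param studyBackground the study's gene universe.
#' @return list with \code{table} (2x2), \code{statistic}, \code{p},
#'   \code{direction}, \code{log2_fold}, \code{n_background},
#'   \code{unreliable}.
#' @export
chiSquareOverlap <- function(geneList, listBackground = NULL, focalGenes,
                             studyBackground) {
  if (!all(focalGenes %in% studyBackground))
    stop("focal genes must be a subset of the study background")
  bg <- if (is.null(listBackground)) studyBackground
        else intersect(studyBackground, listBackground)
  if (length(bg) < 4L) stop("harmonized background too small")
  inList <- bg %in% geneList
  inFocal <- bg %in% focalGenes
  tab <- table(factor(inList, c(TRUE, FALSE)), factor(inFocal, c(TRUE, FALSE)),
               dnn = c("in_list", "in_focal"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, statistic = 0, p = 1, direction = "over",
                log2_fold = NA_real_, n_background = length(bg),
                unreliable = TRUE))
  suppressWarnings(ct <- chisq.test(tab, correct = FALSE))
  expected11 <- ct$expected[1L, 1L]
  obs11 <- tab[1L, 1L]
  stat <- unname(ct$statistic)
  p <- unname(ct$p.value)
  list(
    table = tab,
    statistic = stat,
    p = p,
    direction = if (obs11 >= expected11) "over" else "under",
    log2_fold = if (expected11 > 0) log2(obs11 / expected11) else NA_real_,
    n_background = length(bg),
    unreliable = any(ct$expected < 1)
  )
}

#' Write an enrichment table as TSV
#' @param res an \linkS4class{EnrichmentResult}.
#' @param file output path.
#' @export
writeEnrichmentTsv <- function(res, file) {
  write.table(as.data.frame(enrichmentTable(res)), file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}
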