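#' Read a tab-separated trait table
#'
#' Expected layout: header row; first column \code{species_id}; remaining
#' columns raw trait values (MLSP in years, body and brain mass in grams,
#' gestation time and age at sexual maturity in days); missing values "NA".
#'
#' @param file path to the TSV.
#' @return data.frame with species ids as rownames.
#' @export
readTraitTable <- function(file) {
  d <- read.delim(file, na.strings = "NA", check.names = FALSE,
                  stringsAsFactors = FALSE)
  rownames(d) <- d[[1L]]
  d[[1L]] <- NULL
  d
}

#' Read a family-count TSV (families in rows, species in columns)
#' @param file path; first column family_id.
#' @return integer matrix with dimnames.
#' @export
readCountMatrix <- function(file) {
  d <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' Read per-species genome completeness scores
#' @param file TSV with columns species_id, busco_completeness (fraction 0-1).
#' @return named numeric vector.
#' @export
readCompletenessTable <- function(file) {
  d <- read.delim(file, stringsAsFactors = FALSE)
  v <- as.numeric(d[[2L]])
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("completeness scores must be fractions in [0,1]")
  setNames(v, d[[1L]])
}

#' Filter species on genome completeness
#'
#' Keeps species whose completeness score is strictly greater than the
#' threshold (the inclusion rule is "higher than", so a score exactly at the
#' threshold is excluded).
#'
#' @param scores named numeric vector of fractions in [0,1].
#' @param threshold fraction in (0,1); default 0.80.
#' @return character vector of retained species ids.
#' @export
filterSpeciesByCompleteness <- function(scores, threshold = 0.80) {
  stopifnot(threshold > 0, threshold < 1)
  if (any(scores < 0 | scores > 1, na.rm = TRUE))
    stop("completeness scores must lie in [0,1]")
  keep <- names(scores)[!is.na(scores) & scores > threshold]
  if (!length(keep)) stop("no species passes the completeness threshold")
  keep
}

#' Gene-family filter cascade
#'
#' Retains families that (i) vary in gene number across species, (ii) reach at
#' least \code{minMaxCount} genes in some species, and (iii) are present
#' (count >= 1) in at least \code{ceiling(presenceFraction * n_species)}
#' species, ruling out lineage-specific families. The three predicates
#' commute; the function is idempotent.
#'
#' @param counts integer matrix, families x species (already restricted to the
#'   retained species set).
#' @param presenceFraction default 0.80.
#' @param minMaxCount default 3.
#' @return the filtered matrix (possibly with zero rows).
#' @export
filterFamilies <- function(counts, presenceFraction = 0.80, minMaxCount = 3L) {
  if (nrow(counts) == 0L) return(counts)
  n <- ncol(counts)
  v <- apply(counts, 1L, var) > 0
  mx <- apply(counts, 1L, max) >= minMaxCount
  pres <- rowSums(counts >= 1L) >= ceiling(presenceFraction * n)
  kept <- counts[v & mx & pres, , drop = FALSE]
  message(nrow(kept), " of ", nrow(counts), " families retained by filters")
  kept
}

#' Add log10 columns for the raw traits
#'
#' Adds a \code{log10_<trait>} column for each listed raw trait. Raw values
#' must be strictly positive where present; NA propagates.
#'
#' @param traits data.frame with species rownames.
#' @param cols columns to transform (default: all numeric raw-trait columns,
#'   i.e. every numeric column not already log10_ or a residual).
#' @return the trait table with the added columns.
#' @export
log10Traits <- function(traits, cols = NULL) {
  if (is.null(cols)) {
    num <- vapply(traits, is.numeric, logical(1L))
    cols <- names(traits)[num & !startsWith(names(traits), "log10_") &
                            names(traits) != "relative_brain_size"]
  }
  for (cl in cols) {
    v <- traits[[cl]]
    bad <- !is.na(v) & v <= 0
    if (any(bad))
      stop("non-positive ", cl, " for species: ",
           paste(rownames(traits)[bad], collapse = ", "))
    traits[[paste0("log10_", cl)]] <- log10(v)
  }
  traits
}

#' Relative brain size: allometric residuals
#'
#' Fits an ordinary (non-phylogenetic) least-squares regression of
#' log10(brain mass) on log10(body mass) over the species with both masses and
#' stores the residuals as \code{relative_brain_size} — brain size controlled
#' for body-size allometry. Species missing either mass get NA.
#'
#' @param traits data.frame with columns \code{brain_mass} and
#'   \code{body_mass} (grams) or their log10_ columns.
#' @return the trait table with the \code{relative_brain_size} column.
#' @export
relativeBrainSize <- function(traits) {
  lb <- if ("log10_brain_mass" %in% names(traits)) traits$log10_brain_mass
        else log10(traits$brain_mass)
  lm_ <- if ("log10_body_mass" %in% names(traits)) traits$log10_body_mass
         else log10(traits$body_mass)
  ok <- !is.na(lb) & !is.na(lm_)
  if (sum(ok) < 3L) stop("need >= 3 species with both brain and body mass")
  if (var(lm_[ok]) == 0) stop("all body masses identical: slope undefined")
  fit <- lm.fit(cbind(1, lm_[ok]), lb[ok])
  res <- rep(NA_real_, nrow(traits))
  res[ok] <- fit$residuals
  traits$relative_brain_size <- res
  traits
}
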