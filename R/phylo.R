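#' Read a Newick tree
#'
#' Parses a Newick string (or file) into an \code{ape::phylo} object and
#' validates it for use here: branch lengths on every edge, unique non-empty
#' tip labels, single root. Square-bracket comments are ignored by the parser.
#' Ultrametricity is checked with a relative tolerance of 1e-6 on root-to-tip
#' depths; violations raise a warning, not an error, since GLS is defined for
#' any positive semi-definite covariance.
#'
#' @param text a Newick string, or \code{file} a path.
#' @param file optional path to a Newick file (used if \code{text} missing).
#' @return a rooted \code{phylo} object.
#' @examples
#' tr <- readNewick("((A:1,B:1):1,C:2);")
#' @export
readNewick <- function(text, file = NULL) {
  tr <- if (is.null(file)) {
    tryCatch(read.tree(text = text),
             error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  } else read.tree(file)
  if (is.null(tr)) stop("malformed Newick: parser returned no tree")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length))
    stop("every edge must carry a branch length")
  if (any(tr$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip label: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (any(!nzchar(tr$tip.label))) stop("empty tip label")
  .warnIfNotUltrametric(tr)
  tr
}

#' Write a tree as Newick
#'
#' @param tree a \code{phylo} object.
#' @param file optional output path; if NULL the string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
writeNewick <- function(tree, file = NULL) {
  s <- write.tree(tree, digits = 15)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

.warnIfNotUltrametric <- function(tree, tol = 1e-6) {
  if (Ntip(tree) >= 2L && !is.ultrametric(tree, option = 2, tol = tol))
    warning("tree is not ultrametric within relative tolerance ", tol)
  invisible(tree)
}

#' Prune a tree to a species subset
#'
#' Drops all tips outside \code{keep}, suppressing unary internal nodes by
#' summing their branch lengths, so pairwise distances among kept tips are
#' unchanged.
#'
#' @param tree a \code{phylo}.
#' @param keep character vector of tip labels to retain (>= 2, subset of tips).
#' @return the pruned \code{phylo}.
#' @export
pruneTo <- function(tree, keep) {
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing))
    stop("labels not in tree: ", paste(sort(missing), collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 tips to keep")
  if (setequal(keep, tree$tip.label)) return(tree)
  keep.tip(tree, keep)
}

# parent vector indexed by node id (root gets NA), and edge length to parent
.parentTable <- function(tree) {
  nn <- Ntip(tree) + tree$Nnode
  parent <- rep(NA_integer_, nn)
  plen <- rep(NA_real_, nn)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  plen[tree$edge[, 2L]] <- tree$edge.length
  list(parent = parent, plen = plen)
}

#' Brownian-motion covariance of a phylogeny
#'
#' Under Brownian trait evolution the covariance between two tips is the
#' shared branch length from the root to their most recent common ancestor;
#' the variance of a tip is its root-to-tip distance. Computed by walking
#' root-to-tip paths on the tree's parent table; species order is the tree's
#' tip order.
#'
#' @param tree a \code{phylo} with >= 2 tips and non-negative branch lengths.
#' @return a symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @examples
#' brownianCovariance(readNewick("((A:1,B:1):1,C:2);"))
#' @export
brownianCovariance <- function(tree) {
  if (Ntip(tree) < 2L) stop("need >= 2 tips")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  n <- Ntip(tree)
  pt <- .parentTable(tree)
  depth <- node.depth.edgelength(tree)  # root-to-node path lengths
  # ancestor chains per tip (tip first, root last)
  chains <- lapply(seq_len(n), function(i) {
    ch <- i
    while (!is.na(pt$parent[ch[length(ch)]])) ch <- c(ch, pt$parent[ch[length(ch)]])
    ch
  })
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  diag(V) <- depth[seq_len(n)]
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      anc_i <- chains[[i]]
      for (j in seq.int(i + 1L, n)) {
        mrca <- anc_i[match(TRUE, anc_i %in% chains[[j]])]
        V[i, j] <- V[j, i] <- depth[mrca]
      }
    }
  }
  V
}

# post-order contrast recursion; handles polytomies by combining children
# sequentially (zero-length internal edges), children ordered lexicographically
# by their smallest descendant tip label.
.contrastRecursion <- function(tree, x) {
  n <- Ntip(tree)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- numeric(n + tree$Nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  contrasts <- numeric(0)
  cnodes <- integer(0)
  cvar <- numeric(0)
  minlab <- character(n + tree$Nnode)

  rec <- function(node) {
    if (node <= n) {
      minlab[node] <<- tree$tip.label[node]
      return(c(unname(x[tree$tip.label[node]]), elen[node]))
    }
    kids <- children[[as.character(node)]]
    states <- lapply(kids, rec)
    ord <- order(vapply(kids, function(k) minlab[k], character(1L)))
    minlab[node] <<- minlab[kids[ord[1L]]]
    states <- states[ord]
    cur <- states[[1L]]
    for (s in states[-1L]) {
      v1 <- cur[2L]; v2 <- s[2L]
      contrasts <<- c(contrasts, (cur[1L] - s[1L]) / sqrt(v1 + v2))
      cnodes <<- c(cnodes, node)
      cvar <<- c(cvar, v1 + v2)
      # ancestral value and extended branch length of the merged pair
      cur <- c((cur[1L] * v2 + s[1L] * v1) / (v1 + v2), v1 * v2 / (v1 + v2))
    }
    c(cur[1L], cur[2L] + elen[node])
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  rec(root)
  list(contrasts = contrasts, nodes = cnodes, variances = cvar)
}

#' Felsenstein's phylogenetically independent contrasts
#'
#' Standardized contrasts by the pruning recursion: at each internal node the
#' difference of the two daughter values divided by the square root of their
#' summed (extended) branch lengths; the node's ancestral value is the
#' variance-weighted mean and its branch is extended by the product/sum rule.
#' Polytomies are combined pairwise in deterministic lexicographic order
#' (equivalent to resolving them with zero-length internal edges), so a tree
#' with n tips always yields n - 1 contrasts.
#'
#' @param tree a rooted \code{phylo}.
#' @param x named numeric trait vector covering every tip.
#' @return list with \code{contrasts}, \code{nodes} (internal node ids) and
#'   \code{variances} (expected variances, summed branch lengths).
#' @examples
#' tr <- readNewick("(A:1,B:1);")
#' independentContrasts(tr, c(A = 3, B = 1))$contrasts  # (3-1)/sqrt(2)
#' @export
independentContrasts <- function(tree, x) {
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss))
    stop("missing trait value for tip(s): ", paste(miss, collapse = ", "))
  if (anyNA(x[tree$tip.label]))
    stop("NA trait value for tip(s): ",
         paste(tree$tip.label[is.na(x[tree$tip.label])], collapse = ", "))
  .contrastRecursion(tree, x)
}

#' Correlation of two traits through independent contrasts
#'
#' Contrasts have an arbitrary sign per node, so the correlation is computed
#' through the origin: r = sum(cx*cy) / sqrt(sum(cx^2) sum(cy^2)). The test
#' uses t = r * sqrt(df / (1 - r^2)) with df = (number of contrasts) - 1 (one
#' df lost to the through-origin slope), two-sided.
#'
#' @param tree a rooted \code{phylo} with >= 3 tips.
#' @param x,y named trait vectors covering every tip.
#' @return list with \code{r}, \code{p}, \code{df} and a \code{degenerate}
#'   flag (TRUE when either contrast set has zero variance, in which case r
#'   and p are NA rather than a silent 0).
#' @export
picCorrelation <- function(tree, x, y) {
  if (Ntip(tree) < 3L) stop("need >= 3 tips")
  cx <- independentContrasts(tree, x)$contrasts
  cy <- independentContrasts(tree, y)$contrasts
  sxx <- sum(cx^2); syy <- sum(cy^2)
  df <- length(cx) - 1L
  if (sxx == 0 || syy == 0)
    return(list(r = NA_real_, p = NA_real_, df = df, degenerate = TRUE))
  r <- sum(cx * cy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tval), df)
  }
  list(r = r, p = p, df = df, degenerate = FALSE)
}
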