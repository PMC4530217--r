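#' Gene-gene Pearson correlation matrix
#'
#' Pearson correlation across samples between all gene pairs. Zero-variance
#' genes are dropped with a warning (correlation undefined); fewer than three
#' samples is an error.
#'
#' @param x Numeric matrix, genes x samples (typically log2(RPKM + 1)), or an
#'   \code{\link{expression_set}} whose raw values are used as-is.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  if (inherits(x, "expression_set")) x <- x$values
  if (ncol(x) < 3L) stop("correlation needs >= 3 samples")
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s)")
    x <- x[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(x))
  diag(r) <- 1
  r
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted-network adjacency a_ij = |r_ij|^power with unit
#' diagonal. The default power 12 is the standard soft threshold for
#' unsigned networks.
#'
#' @param corr Symmetric correlation matrix with entries in [-1, 1].
#' @param power Integer soft-threshold exponent (>= 1).
#' @return Adjacency matrix with entries in [0, 1], attribute \code{"power"}.
#' @export
adjacency <- function(corr, power = 12L) {
  if (power < 1) stop("'power' must be >= 1")
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix must be symmetric")
  a <- abs(corr)^power
  diag(a) <- 1
  attr(a, "power") <- power
  a
}

#' Topological overlap matrix
#'
#' Unsigned TOM: for i != j,
#' \deqn{TOM_{ij} = (l_{ij} + a_{ij}) / (min(k_i, k_j) + 1 - a_{ij})}
#' with \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; the diagonal is 1. Computed via a
#' matrix product over the zero-diagonal adjacency.
#'
#' @param adj Symmetric adjacency matrix with entries in [0, 1], unit
#'   diagonal.
#' @return Symmetric TOM with entries in [0, 1] and unit diagonal.
#' @export
topological_overlap <- function(adj) {
  if (max(abs(adj - t(adj))) > 1e-8) stop("adjacency matrix must be symmetric")
  a0 <- adj
  diag(a0) <- 0
  l <- a0 %*% a0                      # diag(a0)=0 kills the u=i and u=j terms
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (l + a0) / (kmin + 1 - a0)
  tom <- (tom + t(tom)) / 2           # symmetrize numerical noise
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Average-linkage dendrogram on TOM dissimilarity
#'
#' Hierarchical clustering of genes on d = 1 - TOM with average linkage,
#' the standard tree for weighted coexpression module detection.
#'
#' @param tom Topological overlap matrix.
#' @return An \code{\link[stats]{hclust}} object.
#' @export
cluster_dendrogram <- function(tom) {
  if (nrow(tom) < 3L) stop("clustering needs >= 3 genes")
  stats::hclust(stats::as.dist(1 - tom), method = "average")
}

#' Module eigengene
#'
#' First principal component of a module over samples: member genes are
#' standardized across samples (mean 0, variance 1), the first right-singular
#' vector of the member x sample matrix is taken, scaled to unit length, and
#' sign-flipped so that its correlation with the module's mean standardized
#' profile is nonnegative. Zero-variance members are excluded with a warning.
#'
#' @param x Numeric matrix, genes x samples (expression scale used for the
#'   fit).
#' @param genes Character vector of member gene ids (>= 2).
#' @return Numeric vector over samples (unit norm) with attribute
#'   \code{"var_explained"}.
#' @export
module_eigengene <- function(x, genes) {
  m <- x[genes, , drop = FALSE]
  v <- apply(m, 1L, stats::var)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " zero-variance member(s)")
    m <- m[v > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("module eigengene needs >= 2 members with variance")
  z <- t(scale(t(m)))
  sv <- svd(z, nu = 0L, nv = 1L)
  e <- sv$v[, 1L]
  mp <- colMeans(z)
  if (sum(e * mp) < 0) e <- -e
  e <- e / sqrt(sum(e^2))
  names(e) <- colnames(x)
  attr(e, "var_explained") <- sv$d[1L]^2 / sum(sv$d^2)
  e
}

module_eigengene_matrix <- function(x, assignment) {
  labs <- sort(unique(assignment[assignment != 0L]))
  me <- matrix(NA_real_, length(labs), ncol(x),
               dimnames = list(as.character(labs), colnames(x)))
  for (l in labs)
    me[as.character(l), ] <- module_eigengene(x, names(assignment)[assignment == l])
  me
}

#' Merge highly similar modules
#'
#' Iteratively merges the module pair with the highest eigengene correlation
#' while any pair exceeds \code{cor_threshold}, recomputing the merged
#' eigengene after every merge. Ties are broken by the lexicographically
#' smaller label pair; the merged module keeps the smaller label. On return,
#' all pairwise eigengene correlations are <= \code{cor_threshold} and
#' modules are relabeled 1..K by decreasing size (ties by smallest member
#' gene id).
#'
#' @param x Numeric matrix, genes x samples, on the fitting scale.
#' @param assignment Named integer vector gene -> module label (0 =
#'   unassigned).
#' @param cor_threshold Merge when eigengene correlation exceeds this value.
#' @return List with \code{assignment} (relabeled) and \code{eigengenes}
#'   (module x sample matrix).
#' @export
merge_close_modules <- function(x, assignment, cor_threshold = 0.9) {
  a <- assignment
  labs <- sort(unique(a[a != 0L]))
  if (length(labs) == 0L)
    return(list(assignment = a, eigengenes = matrix(numeric(0), 0L, ncol(x))))
  me <- module_eigengene_matrix(x, a)
  while (nrow(me) >= 2L) {
    cc <- stats::cor(t(me))
    cc[is.na(cc)] <- -Inf
    diag(cc) <- -Inf
    if (max(cc) <= cor_threshold) break
    idx <- which(cc == max(cc), arr.ind = TRUE)
    pair <- t(apply(idx, 1L, function(r) sort(as.integer(rownames(me))[r])))
    pair <- pair[order(pair[, 1L], pair[, 2L]), , drop = FALSE][1L, ]
    a[a == pair[2L]] <- pair[1L]
    me <- module_eigengene_matrix(x, a)
  }
  relabel_modules(a, x)
}

# relabel modules 1..K by decreasing size; ties by smallest member gene id
relabel_modules <- function(assignment, x) {
  a <- assignment
  labs <- unique(a[a != 0L])
  if (length(labs) == 0L)
    return(list(assignment = a, eigengenes = matrix(numeric(0), 0L, ncol(x),
                                                    dimnames = list(NULL, colnames(x)))))
  sizes <- vapply(labs, function(l) sum(a == l), integer(1L))
  firsts <- vapply(labs, function(l) min(names(a)[a == l]), character(1L))
  ord <- labs[order(-sizes, firsts)]
  new <- a
  for (i in seq_along(ord)) new[a == ord[i]] <- i
  list(assignment = new, eigengenes = module_eigengene_matrix(x, new))
}
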