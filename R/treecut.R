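#' Dynamic hybrid tree cut
#'
#' Flat module extraction from an average-linkage dendrogram in two stages.
#'
#' Stage 1 selects branches of the merge tree as module cores. Merges above
#' \code{cut_height} (default 0.99 of the tallest merge) always split. Below
#' it, a branch qualifies as a module when (i) it holds at least
#' \code{min_size} leaves, (ii) its scatter -- the mean height of its internal
#' merges -- does not exceed a threshold, and (iii) its gap -- the height at
#' which it joins its parent minus its own top merge height -- is large
#' enough. Scatter and gap thresholds are set on the height scale normalized
#' between the 5th percentile of merge heights and \code{cut_height};
#' \code{deep_split} (0--4) maps to a maximum core scatter of
#' (0.64, 0.73, 0.82, 0.91, 0.95) with minimum gap \code{(1 - scatter) * 3/4}.
#' Among nested qualifying branches the deepest ones win: a branch becomes a
#' module only if none of its sub-branches already did.
#'
#' Stage 2 attaches leftover genes: an unassigned gene joins the module with
#' the smallest average dissimilarity to its members, provided that average
#' does not exceed the module's radius (the largest average dissimilarity of
#' any current member to its co-members). Genes closer to no module keep
#' label 0.
#'
#' @param dendro \code{\link[stats]{hclust}} tree built on \code{dissim}.
#' @param dissim Symmetric dissimilarity matrix (1 - TOM) the tree was built
#'   from, with gene ids as dimnames.
#' @param deep_split Integer 0--4; larger values split more finely.
#' @param min_size Minimum module size (>= 2).
#' @param cut_height Maximum merge height still considered for module cores;
#'   default \code{0.99 * max(dendro$height)}.
#' @return Named integer vector gene -> module label; 0 means unassigned.
#'   Modules are labeled 1..K by decreasing size (ties by smallest gene id).
#' @export
dynamic_hybrid_cut <- function(dendro, dissim, deep_split = 4L, min_size = 30L,
                               cut_height = NULL) {
  if (min_size < 2L) stop("'min_size' must be >= 2")
  if (!deep_split %in% 0:4) stop("'deep_split' must be in 0..4")
  n <- length(dendro$order)
  if (!is.null(dendro$labels) && !identical(dendro$labels, rownames(dissim)))
    dissim <- dissim[dendro$labels, dendro$labels]
  h <- dendro$height
  if (is.null(cut_height)) cut_height <- 0.99 * max(h)
  max_scatter <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deep_split + 1L]
  min_gap <- (1 - max_scatter) * 3 / 4
  ref_h <- unname(stats::quantile(h, 0.05, names = FALSE))
  range_h <- max(cut_height - ref_h, 0)   # degenerate trees: thresholds collapse
  abs_scatter <- ref_h + max_scatter * range_h
  abs_gap <- min_gap * range_h

  # per-merge-node statistics, bottom-up
  merge <- dendro$merge
  size <- integer(n - 1L)
  hsum <- numeric(n - 1L)   # sum of internal merge heights
  nmrg <- integer(n - 1L)   # number of internal merges
  for (i in seq_len(n - 1L)) {
    kids <- merge[i, ]
    sz <- hs <- nm <- 0
    for (k in kids) {
      if (k < 0) sz <- sz + 1L
      else { sz <- sz + size[k]; hs <- hs + hsum[k]; nm <- nm + nmrg[k] }
    }
    size[i] <- sz
    hsum[i] <- hs + h[i]
    nmrg[i] <- nm + 1L
  }
  scatter <- hsum / nmrg

  qualifies <- function(i, parent_h) {
    size[i] >= min_size && h[i] <= cut_height &&
      scatter[i] <= abs_scatter && (parent_h - h[i]) >= abs_gap
  }

  # post-order walk: a node becomes a module core only if no descendant did
  assignment <- integer(n)
  names(assignment) <- if (is.null(dendro$labels)) rownames(dissim) else dendro$labels
  next_label <- 0L
  # found[i]: TRUE if the subtree rooted at merge i contains a module core;
  # a node is a core iff no descendant is and it qualifies itself
  found <- logical(n - 1L)
  parent_h <- rep(cut_height, n - 1L)
  for (i in seq_len(n - 1L))
    for (k in merge[i, ]) if (k > 0) parent_h[k] <- h[i]
  is_core <- logical(n - 1L)
  for (i in seq_len(n - 1L)) {
    kids <- merge[i, ]
    kid_found <- any(vapply(kids, function(k) k > 0 && found[k], logical(1L)))
    if (!kid_found && qualifies(i, parent_h[i])) {
      is_core[i] <- TRUE
      found[i] <- TRUE
    } else {
      found[i] <- found[i] || kid_found
    }
  }
  leaves_of <- function(i) {
    out <- integer(0)
    stack <- i
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (k in merge[j, ]) {
        if (k < 0) out <- c(out, -k) else stack <- c(stack, k)
      }
    }
    out
  }
  for (i in which(is_core)) {
    next_label <- next_label + 1L
    assignment[leaves_of(i)] <- next_label
  }

  # stage 2: PAM-like attachment of unassigned genes within module radius
  if (next_label > 0L && any(assignment == 0L)) {
    un <- which(assignment == 0L)
    labs <- seq_len(next_label)
    radius <- numeric(next_label)
    avg <- matrix(0, length(un), next_label)
    for (l in labs) {
      mem <- which(assignment == l)
      dm <- dissim[mem, mem, drop = FALSE]
      radius[l] <- max(rowSums(dm) / (length(mem) - 1L))
      avg[, l] <- rowMeans(dissim[un, mem, drop = FALSE])
    }
    best <- max.col(-avg, ties.method = "first")
    ok <- avg[cbind(seq_along(un), best)] <= radius[best]
    assignment[un[ok]] <- best[ok]
  }
  relabel_assignment(assignment)
}

# stable relabel 1..K by decreasing size, ties by smallest member gene id
relabel_assignment <- function(a) {
  labs <- unique(a[a != 0L])
  if (!length(labs)) return(a)
  sizes <- vapply(labs, function(l) sum(a == l), integer(1L))
  firsts <- vapply(labs, function(l) min(names(a)[a == l]), character(1L))
  ord <- labs[order(-sizes, firsts)]
  new <- a
  for (i in seq_along(ord)) new[a == ord[i]] <- i
  new
}
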