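#' Fit stage-specific coexpression modules
#'
#' The module-detection core: builds an unsigned weighted coexpression
#' network from the (optionally log-transformed) expression values, extracts
#' modules from the topological-overlap dendrogram with the dynamic hybrid
#' tree cut, merges modules whose eigengenes correlate above
#' \code{merge_cor}, correlates every merged eigengene with the one-hot
#' stage indicators, and assigns each qualifying module to the stage it
#' correlates with best. Same-stage modules are merged into stage gene sets
#' and hub genes (gene-eigengene correlation above \code{hub_r}) are
#' reported per module.
#'
#' @param es An \code{\link{expression_set}} (already filtered/normalized as
#'   desired).
#' @param power Soft-threshold exponent for the adjacency (default 12).
#' @param deep_split Dynamic tree cut sensitivity, 0--4 (default 4).
#' @param min_size Minimum module size (default 30).
#' @param merge_cor Eigengene correlation above which modules merge
#'   (default 0.9).
#' @param r_min,p_max Module-stage correlation and p thresholds for stage
#'   assignment (defaults 0.7 and 0.01; the stricter preset r > 0.6,
#'   p < 0.001 can be set here).
#' @param hub_r,hub_p Gene-eigengene thresholds for hub genes (defaults 0.9
#'   and 0.01).
#' @param transform \code{"log2p1"} (correlate on log2(RPKM + 1), default)
#'   or \code{"raw"}.
#' @return Object of class \code{"stage_modules"}: assignment (gene ->
#'   module, 0 unassigned), eigengenes, sizes, dendrogram, stage_map,
#'   unassigned_modules, stage_sets, provenance, hubs, params, and the
#'   fitting-scale matrix \code{x}.
#' @seealso \code{\link{stage_conservation}} for the downstream
#'   evolutionary analysis.
#' @export
fit_stage_modules <- function(es, power = 12L, deep_split = 4L, min_size = 30L,
                              merge_cor = 0.9, r_min = 0.7, p_max = 0.01,
                              hub_r = 0.9, hub_p = 0.01,
                              transform = c("log2p1", "raw")) {
  transform <- match.arg(transform)
  x <- if (transform == "log2p1") log2(es$values + 1) else es$values
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s) before fitting")
    x <- x[v > 0, , drop = FALSE]
  }
  r <- correlation_matrix(x)
  tom <- topological_overlap(adjacency(r, power))
  dendro <- cluster_dendrogram(tom)
  assign0 <- dynamic_hybrid_cut(dendro, 1 - tom, deep_split, min_size)
  merged <- merge_close_modules(x, assign0, merge_cor)
  assignment <- merged$assignment
  me <- merged$eigengenes
  stage_order <- intersect(ped_stages(), unique(es$stage))
  if (!length(stage_order)) stage_order <- unique(es$stage)
  ind <- stage_indicators(es$stage, stage_order)
  if (nrow(me)) {
    cp <- correlate_modules_to_stages(me, ind)
    am <- assign_modules(cp$correlation, cp$p_value, r_min, p_max)
  } else {
    cp <- list(correlation = matrix(numeric(0), 0, length(stage_order)),
               p_value = matrix(numeric(0), 0, length(stage_order)))
    am <- list(map = data.frame(module = character(0), stage = character(0),
                                correlation = numeric(0), p_value = numeric(0)),
               unassigned = character(0))
  }
  sets <- build_stage_gene_sets(am$map, assignment, stage_order)
  hubs <- lapply(rownames(me), function(l)
    hub_genes(x[names(assignment)[assignment == as.integer(l)], , drop = FALSE],
              me[l, ], hub_r, hub_p))
  names(hubs) <- rownames(me)
  structure(list(
    assignment = assignment,
    eigengenes = me,
    sizes = table(factor(assignment[assignment != 0L])),
    dendrogram = dendro,
    stage_correlation = cp$correlation,
    stage_p = cp$p_value,
    stage_map = am$map,
    unassigned_modules = am$unassigned,
    stage_sets = sets$sets,
    provenance = sets$provenance,
    hubs = hubs,
    stage_order = stage_order,
    sample_stage = es$stage,
    x = x,
    params = list(power = power, deep_split = deep_split, min_size = min_size,
                  merge_cor = merge_cor, r_min = r_min, p_max = p_max,
                  hub_r = hub_r, hub_p = hub_p, transform = transform)),
    class = "stage_modules")
}

#' @export
print.stage_modules <- function(x, ...) {
  k <- nrow(x$eigengenes)
  cat("stage_modules fit: ", length(x$assignment), " genes, ", k, " modules (",
      sum(x$assignment == 0L), " genes unassigned)\n", sep = "")
  cat("modules assigned to a stage: ", nrow(x$stage_map), " of ", k, "\n",
      sep = "")
  sz <- vapply(x$stage_sets, length, integer(1L))
  cat("stage set sizes:\n")
  print(sz)
  invisible(x)
}

#' @export
summary.stage_modules <- function(object, ...) {
  labs <- rownames(object$eigengenes)
  map <- object$stage_map
  out <- data.frame(
    module = labs,
    size = as.integer(object$sizes[labs]),
    stage = map$stage[match(labs, map$module)],
    stage_correlation = map$correlation[match(labs, map$module)],
    stage_p = map$p_value[match(labs, map$module)],
    n_hubs = vapply(object$hubs[labs], length, integer(1L)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
plot.stage_modules <- function(x, ...) {
  op <- graphics::par(mfrow = c(2L, 1L), mar = c(1, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$dendrogram, labels = FALSE, hang = -1,
                 main = "TOM dissimilarity dendrogram", xlab = "", sub = "")
  ord <- x$dendrogram$order
  cols <- c("grey80", grDevices::hcl.colors(max(1L, nrow(x$eigengenes)),
                                            "Dark 3"))
  graphics::par(mar = c(2, 4, 0, 1))
  graphics::image(matrix(x$assignment[ord], ncol = 1L),
                  col = cols[sort(unique(x$assignment)) + 1L],
                  axes = FALSE, ylab = "module")
  invisible(x)
}

#' Stage-level evolutionary conservation analysis
#'
#' Runs the four conservation indices over per-stage gene sets: the median
#' dN/dS resampling test, Fisher-exact enrichment of the four gene-age
#' intervals, Fisher-exact enrichment of zebrafish ortholog classes (with
#' many2many genes removed first), and upper-tail hypergeometric enrichment
#' of TF and promoter-HCNE flags. When every stage yields a reliable dN/dS
#' test the per-stage medians are summarized into the conservation trend.
#'
#' @param stage_sets Named list stage -> character vector of gene ids (e.g.
#'   the \code{stage_sets} element of a \code{\link{fit_stage_modules}}
#'   fit, or the fit object itself).
#' @param annot Annotation table from \code{\link{gene_annotation_table}}.
#' @param stage_order Stages in developmental order.
#' @param n_perm Permutations for the resampling test.
#' @param seed Base seed; stage i uses \code{seed + i - 1}.
#' @param alternative Sidedness of the resampling p (see
#'   \code{\link{median_dnds_test}}).
#' @param alpha_resample Significance threshold recorded for the resampling
#'   test (default 0.05).
#' @param alpha_fisher Threshold for the enrichment tests (default 0.01).
#' @return Object of class \code{"stage_conservation"} with elements
#'   \code{dnds} (data frame), \code{dnds_tests} (full per-stage results),
#'   \code{age}, \code{ortholog}, \code{tf}, \code{hcne} (data frames with
#'   a stage column) and \code{trend} (a \code{\link{conservation_trend}}
#'   summary, or NULL if some stage was unreliable).
#' @export
stage_conservation <- function(stage_sets, annot, stage_order = NULL,
                               n_perm = 10000L, seed = 1L,
                               alternative = c("two.sided", "directional"),
                               alpha_resample = 0.05, alpha_fisher = 0.01) {
  alternative <- match.arg(alternative)
  if (inherits(stage_sets, "stage_modules")) {
    if (is.null(stage_order)) stage_order <- stage_sets$stage_order
    stage_sets <- stage_sets$stage_sets
  }
  if (is.null(stage_order)) stage_order <- names(stage_sets)
  tests <- list()
  rows <- list()
  for (i in seq_along(stage_order)) {
    s <- stage_order[i]
    tst <- median_dnds_test(stage_sets[[s]], annot, n_perm = n_perm,
                            seed = seed + i - 1L, alternative = alternative)
    tests[[s]] <- tst
    rows[[s]] <- data.frame(
      stage = s, n_genes_with_dnds = tst$n_genes_with_dnds,
      observed_median = tst$observed_median,
      background_median = tst$background_median,
      ci_low = tst$ci_low, ci_high = tst$ci_high, p_value = tst$p_value,
      direction = tst$direction,
      significant = !is.na(tst$p_value) && tst$p_value < alpha_resample,
      reliable = tst$reliable, stringsAsFactors = FALSE)
  }
  dnds <- do.call(rbind, rows)
  rownames(dnds) <- NULL
  per_stage_df <- function(f) {
    out <- do.call(rbind, lapply(stage_order, function(s) {
      df <- f(s)
      if (is.null(df)) return(NULL)
      cbind(stage = s, df, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  }
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  age <- per_stage_df(function(s)
    safe(category_enrichment(stage_sets[[s]], annot, "age_interval",
                             alpha = alpha_fisher)))
  ortholog <- per_stage_df(function(s)
    safe(category_enrichment(stage_sets[[s]], annot, "ortholog_class",
                             exclude_categories = "many2many",
                             alpha = alpha_fisher)))
  tf <- per_stage_df(function(s)
    safe(tf_hcne_enrichment(stage_sets[[s]], annot, "is_tf",
                            alpha = alpha_fisher)))
  hcne <- per_stage_df(function(s)
    safe(tf_hcne_enrichment(stage_sets[[s]], annot, "has_hcne",
                            alpha = alpha_fisher)))
  trend <- if (all(dnds$reliable)) conservation_trend(tests, stage_order)
    else NULL
  structure(list(dnds = dnds, dnds_tests = tests, age = age,
                 ortholog = ortholog, tf = tf, hcne = hcne, trend = trend,
                 stage_order = stage_order,
                 params = list(n_perm = n_perm, seed = seed,
                               alternative = alternative,
                               alpha_resample = alpha_resample,
                               alpha_fisher = alpha_fisher)),
            class = "stage_conservation")
}

#' @export
print.stage_conservation <- function(x, ...) {
  cat("stage_conservation over", length(x$stage_order), "stages\n")
  cat("median dN/dS by stage:\n")
  print(x$dnds[, c("stage", "n_genes_with_dnds", "observed_median",
                   "p_value", "direction")], digits = 4)
  if (!is.null(x$trend))
    cat("trend pattern:", x$trend$pattern_label, "\n")
  else cat("trend not computed (some stage unreliable)\n")
  invisible(x)
}

#' @export
summary.stage_conservation <- function(object, ...) {
  enr <- rbind(
    cbind(index = "age", object$age),
    cbind(index = "ortholog", object$ortholog),
    cbind(index = "tf", object$tf),
    cbind(index = "hcne", object$hcne))
  rownames(enr) <- NULL
  list(dnds = object$dnds, enrichment = enr, trend = object$trend)
}

#' @export
plot.stage_conservation <- function(x, ...) {
  d <- x$dnds
  idx <- seq_len(nrow(d))
  ylim <- range(c(d$observed_median, d$ci_low, d$ci_high, d$background_median),
                na.rm = TRUE)
  graphics::plot(idx, d$observed_median, type = "b", pch = 19, xaxt = "n",
                 xlab = "", ylab = "median dN/dS", ylim = ylim, ...)
  graphics::axis(1, at = idx, labels = d$stage, las = 2, cex.axis = 0.8)
  graphics::lines(idx, d$ci_low, lty = 2, col = "grey40")
  graphics::lines(idx, d$ci_high, lty = 2, col = "grey40")
  graphics::abline(h = d$background_median[1L], lty = 3, col = "grey40")
  sig <- which(!is.na(d$p_value) & d$p_value < x$params$alpha_resample)
  if (length(sig))
    graphics::text(sig, d$observed_median[sig], "*", pos = 3, cex = 1.4)
  invisible(x)
}
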