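#' Two-sided Fisher exact p for a 2x2 table
#'
#' Exact two-sided p-value for independence in a 2x2 table, computed by
#' scanning the hypergeometric support: the sum of point probabilities of
#' all tables with the observed margins whose probability does not exceed
#' the observed table's (with the customary 1 + 1e-7 relative guard against
#' floating-point ties). Vectorized over table cells; agrees with
#' \code{stats::fisher.test} but is fast enough to sweep the full table
#' space in tests.
#'
#' @param a,b,c,d Cell counts: (a, b) is the first row, (c, d) the second.
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]
    mm <- c[i] + d[i]
    k <- a[i] + c[i]
    supp <- max(0L, k - mm):min(k, m)
    dens <- stats::dhyper(supp, m, mm, k)
    pobs <- dens[match(a[i], supp)]
    min(1, sum(dens[dens <= pobs * (1 + 1e-7)]))
  }, numeric(1L))
}

# upper-tail hypergeometric p: P(X >= q) with q successes drawn
.hyper_upper <- function(q, n_flag, n_total, n_draw) {
  if (n_flag == 0L) return(1)
  stats::phyper(q - 1L, n_flag, n_total - n_flag, n_draw, lower.tail = FALSE)
}

#' Resampling test for the median dN/dS of a stage
#'
#' Compares the observed median dN/dS of a stage's genes against medians of
#' \code{n_perm} equally sized random gene sets drawn without replacement
#' from the background (all genes with a dN/dS value). The empirical
#' p-value carries the +1 finite-sample correction,
#' p_tail = (1 + #more extreme) / (n_perm + 1). The default
#' \code{"two.sided"} p doubles the smaller tail (capped at 1) and is
#' calibrated under the null; \code{"directional"} reports the raw tail
#' probability on the observed side of the background median.
#'
#' @param stage_genes Character vector of the stage's gene ids.
#' @param annot Annotation table from \code{\link{gene_annotation_table}}.
#' @param n_perm Number of random sets.
#' @param seed Integer seed for the draws.
#' @param alternative \code{"two.sided"} (default) or \code{"directional"}.
#' @param conf_level Coverage of the resampled-median band (default 0.95).
#' @return List of class \code{"dnds_resample"}: stage size used, observed
#'   and background medians, band limits, p-value, direction, and the
#'   \code{reliable} flag (FALSE, with no p, when fewer than 5 stage genes
#'   carry a dN/dS value).
#' @export
median_dnds_test <- function(stage_genes, annot, n_perm = 10000L, seed = 1L,
                             alternative = c("two.sided", "directional"),
                             conf_level = 0.95) {
  alternative <- match.arg(alternative)
  bg <- annot$dnds[!is.na(annot$dnds)]
  names(bg) <- rownames(annot)[!is.na(annot$dnds)]
  vals <- bg[intersect(stage_genes, names(bg))]
  k <- length(vals)
  out <- list(n_genes_with_dnds = k,
              observed_median = if (k) stats::median(vals) else NA_real_,
              background_median = stats::median(bg),
              ci_low = NA_real_, ci_high = NA_real_,
              p_value = NA_real_, direction = NA_character_,
              n_permutations = n_perm, seed = seed,
              alternative = alternative, reliable = k >= 5L)
  if (k < 5L) {
    class(out) <- "dnds_resample"
    return(out)
  }
  set.seed(seed)
  nb <- length(bg)
  perm <- vapply(seq_len(n_perm),
                 function(i) stats::median(bg[sample.int(nb, k)]),
                 numeric(1L))
  lo <- (1 + sum(perm <= out$observed_median)) / (n_perm + 1)
  hi <- (1 + sum(perm >= out$observed_median)) / (n_perm + 1)
  out$direction <- if (out$observed_median <= out$background_median)
    "lower" else "higher"
  out$p_value <- if (alternative == "two.sided") min(1, 2 * min(lo, hi))
    else if (out$direction == "lower") lo else hi
  alpha <- (1 - conf_level) / 2
  q <- stats::quantile(perm, c(alpha, 1 - alpha), names = FALSE)
  out$ci_low <- q[1L]
  out$ci_high <- q[2L]
  class(out) <- "dnds_resample"
  out
}

#' @export
print.dnds_resample <- function(x, ...) {
  cat(sprintf("median dN/dS resampling test (k = %d, %d permutations)\n",
              x$n_genes_with_dnds, x$n_permutations))
  cat(sprintf("  observed %.4f vs background %.4f [band %.4f, %.4f]\n",
              x$observed_median, x$background_median, x$ci_low, x$ci_high))
  if (x$reliable)
    cat(sprintf("  p = %.4g (%s, %s)\n", x$p_value, x$alternative, x$direction))
  else cat("  unreliable: fewer than 5 genes with dN/dS\n")
  invisible(x)
}

#' Category enrichment of a stage gene set (Fisher exact)
#'
#' For each category of a per-gene factor (age interval or ortholog class),
#' builds the 2x2 table (in-stage & in-category, in-stage & out,
#' out-of-stage & in-category, out-of-stage & out) over the background of
#' genes carrying the field, and reports the two-sided Fisher exact p plus
#' the observed-minus-expected proportion
#' observed_count / stage_size - background_count / background_size.
#' Categories listed in \code{exclude_categories} (e.g. many2many
#' orthologs) are removed from both stage and background before testing.
#'
#' @param stage_genes Character vector of the stage's gene ids.
#' @param annot Annotation table.
#' @param field \code{"age_interval"} or \code{"ortholog_class"}.
#' @param categories Categories to test, in reporting order; defaults to the
#'   canonical order for the field.
#' @param exclude_categories Categories whose genes are dropped entirely.
#' @param alpha Significance threshold recorded in the output.
#' @return Data frame, one row per category: counts, obs_minus_exp,
#'   p_value, direction, significant.
#' @export
category_enrichment <- function(stage_genes, annot,
                                field = c("age_interval", "ortholog_class"),
                                categories = NULL, exclude_categories = NULL,
                                alpha = 0.01) {
  field <- match.arg(field)
  val <- annot[[field]]
  names(val) <- rownames(annot)
  val <- val[!is.na(val)]
  if (!is.null(exclude_categories)) val <- val[!val %in% exclude_categories]
  if (is.null(categories)) {
    categories <- if (field == "age_interval") age_intervals()
      else c("one2one", "one2many", "many2many", "new_gene")
    categories <- setdiff(intersect(categories, unique(val)),
                          exclude_categories)
  }
  stage <- intersect(stage_genes, names(val))
  if (!length(stage))
    stop("no stage gene carries a value for ", field)
  k <- length(stage)
  n_bg <- length(val)
  sval <- val[stage]
  rows <- lapply(categories, function(cat) {
    obs <- sum(sval == cat)
    tot <- sum(val == cat)
    ome <- obs / k - tot / n_bg
    p <- fisher_exact_2x2(obs, k - obs, tot - obs, (n_bg - k) - (tot - obs))
    data.frame(category = cat, observed_count = obs, stage_size = k,
               background_count = tot, background_size = n_bg,
               obs_minus_exp = ome, p_value = p,
               direction = if (ome >= 0) "over" else "under",
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' TF / HCNE enrichment of a stage gene set (hypergeometric)
#'
#' Upper-tail hypergeometric test for over-representation of a logical flag
#' (transcription-factor status or promoter HCNE presence) in a stage set,
#' against the full annotated gene universe. An all-FALSE background flag
#' yields p = 1 by convention.
#'
#' @param stage_genes Character vector of the stage's gene ids.
#' @param annot Annotation table.
#' @param flag \code{"is_tf"} or \code{"has_hcne"}.
#' @param alpha Significance threshold recorded in the output.
#' @return One-row data frame in the \code{\link{category_enrichment}}
#'   layout.
#' @export
tf_hcne_enrichment <- function(stage_genes, annot,
                               flag = c("is_tf", "has_hcne"), alpha = 0.01) {
  flag <- match.arg(flag)
  val <- annot[[flag]]
  names(val) <- rownames(annot)
  val <- val[!is.na(val)]
  stage <- intersect(stage_genes, names(val))
  k <- length(stage)
  n_bg <- length(val)
  n_flag <- sum(val)
  obs <- sum(val[stage])
  p <- .hyper_upper(obs, n_flag, n_bg, k)
  ome <- if (k) obs / k - n_flag / n_bg else 0
  data.frame(category = flag, observed_count = obs, stage_size = k,
             background_count = n_flag, background_size = n_bg,
             obs_minus_exp = ome, p_value = p,
             direction = if (ome >= 0) "over" else "under",
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' Term over-representation with Bonferroni control
#'
#' Upper-tail hypergeometric test of each term against the annotated
#' background (all genes appearing in the term table), Bonferroni-corrected
#' by the number of tested terms. Only terms passing the corrected
#' threshold are returned.
#'
#' @param stage_genes Character vector of gene ids.
#' @param term_table Data frame with columns \code{gene_id}, \code{term}.
#' @param alpha Corrected-p threshold for reporting.
#' @return Data frame (term, observed, term_size, stage_size,
#'   background_size, p_value, p_bonferroni), sorted by corrected p.
#' @export
term_enrichment <- function(stage_genes, term_table, alpha = 0.01) {
  bg <- unique(term_table$gene_id)
  stage <- intersect(stage_genes, bg)
  terms <- unique(term_table$term)
  n_terms <- length(terms)
  rows <- lapply(terms, function(tm) {
    members <- unique(term_table$gene_id[term_table$term == tm])
    obs <- sum(stage %in% members)
    p <- .hyper_upper(obs, length(members), length(bg), length(stage))
    data.frame(term = tm, observed = obs, term_size = length(members),
               stage_size = length(stage), background_size = length(bg),
               p_value = p, p_bonferroni = min(1, p * n_terms),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$p_bonferroni < alpha, , drop = FALSE]
  out <- out[order(out$p_bonferroni, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize the per-stage conservation trend
#'
#' Converts per-stage median dN/dS into a conservation score (the negated
#' median: higher = more constrained), takes signs of successive score
#' differences (zero within \code{tol}), and labels the run-length-encoded
#' sign pattern, e.g. \code{"up-down-up"}.
#'
#' @param per_stage List of \code{\link{median_dnds_test}} results, or a
#'   data frame with columns \code{stage}, \code{observed_median}.
#' @param stage_order Stages in developmental order; every one must be
#'   present.
#' @param tol Differences within this of zero count as flat.
#' @return List of class \code{"trend_summary"}: stage_order,
#'   conservation_score, direction_changes, pattern_label.
#' @export
conservation_trend <- function(per_stage, stage_order = ped_stages(),
                               tol = 1e-9) {
  if (is.data.frame(per_stage)) {
    med <- stats::setNames(per_stage$observed_median, per_stage$stage)
  } else {
    med <- vapply(per_stage, function(r) r$observed_median, numeric(1L))
    if (is.null(names(med)) || any(!nzchar(names(med))))
      names(med) <- stage_order[seq_along(med)]
  }
  missing <- setdiff(stage_order, names(med))
  if (length(missing) || any(is.na(med[stage_order])))
    stop("missing stage median(s): ",
         paste(union(missing, stage_order[is.na(med[stage_order])]),
               collapse = ", "))
  score <- -med[stage_order]
  d <- diff(score)
  sgn <- ifelse(abs(d) <= tol, 0L, ifelse(d > 0, 1L, -1L))
  runs <- rle(sgn)$values
  lab <- c(`1` = "up", `-1` = "down", `0` = "flat")[as.character(runs)]
  structure(list(stage_order = stage_order,
                 conservation_score = score,
                 direction_changes = sgn,
                 pattern_label = paste(lab, collapse = "-")),
            class = "trend_summary")
}

#' @export
print.trend_summary <- function(x, ...) {
  cat("conservation trend:", x$pattern_label, "\n")
  print(round(x$conservation_score, 4))
  invisible(x)
}
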