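#' One-hot stage indicator matrix
#'
#' Binary stages x samples matrix encoding the stage factor: entry (t, s) is
#' 1 when sample s belongs to stage t. Columns each sum to 1.
#'
#' @param sample_stage Named character vector sample id -> stage label.
#' @param stage_order Stage labels in the order rows should appear; defaults
#'   to the developmental order of the stages present.
#' @return Binary matrix, stages x samples.
#' @export
stage_indicators <- function(sample_stage, stage_order = NULL) {
  if (is.null(stage_order))
    stage_order <- intersect(ped_stages(), unique(sample_stage))
  if (!length(stage_order)) stage_order <- unique(sample_stage)
  unknown <- setdiff(unique(sample_stage), stage_order)
  if (length(unknown))
    stop("unknown stage label(s): ", paste(unknown, collapse = ", "))
  ind <- vapply(stage_order, function(s) as.numeric(sample_stage == s),
                numeric(length(sample_stage)))
  ind <- t(ind)
  dimnames(ind) <- list(stage_order, names(sample_stage))
  ind
}

# two-sided p for a Pearson correlation via the t transform
cor_pvalue <- function(r, n) {
  df <- n - 2L
  denom <- 1 - r^2
  p <- ifelse(denom <= 0, 0,
              2 * stats::pt(abs(r) * sqrt(df / pmax(denom, .Machine$double.xmin)),
                            df = df, lower.tail = FALSE))
  pmin(p, 1)
}

#' Correlate module eigengenes with stage indicators
#'
#' Pearson correlation of each eigengene with each stage's indicator row,
#' with a two-sided p-value from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2
#' degrees of freedom.
#'
#' @param eigengenes Module x sample matrix (rows named by module label).
#' @param indicators Stage x sample binary matrix from
#'   \code{\link{stage_indicators}}; sample order must match.
#' @return List with \code{correlation} and \code{p_value}, both
#'   modules x stages.
#' @export
correlate_modules_to_stages <- function(eigengenes, indicators) {
  if (ncol(eigengenes) != ncol(indicators))
    stop("eigengene and indicator sample dimensions differ")
  if (!is.null(colnames(eigengenes)) && !is.null(colnames(indicators)) &&
      !identical(colnames(eigengenes), colnames(indicators)))
    stop("eigengene and indicator sample order differ")
  if (any(apply(eigengenes, 1L, stats::var) == 0))
    stop("constant eigengene")
  n <- ncol(eigengenes)
  r <- stats::cor(t(eigengenes), t(indicators))
  p <- matrix(cor_pvalue(r, n), nrow(r), ncol(r), dimnames = dimnames(r))
  list(correlation = r, p_value = p)
}

#' Assign modules to developmental stages
#'
#' A module qualifies for every stage with correlation above \code{r_min}
#' and p below \code{p_max}; when it qualifies for several stages it is kept
#' in the stage with the highest correlation (an exact tie goes to the
#' earlier stage in \code{stage_order}, i.e. column order). Modules
#' qualifying nowhere are reported as unassigned.
#'
#' @param corr Modules x stages correlation matrix.
#' @param pvals Matching p-value matrix.
#' @param r_min Correlation threshold (strict).
#' @param p_max P-value threshold (strict).
#' @return List with \code{map}, a data frame (module, stage, correlation,
#'   p_value) for assigned modules, and \code{unassigned}, the leftover
#'   module labels.
#' @export
assign_modules <- function(corr, pvals, r_min = 0.7, p_max = 0.01) {
  mods <- rownames(corr)
  rows <- lapply(seq_along(mods), function(i) {
    ok <- corr[i, ] > r_min & pvals[i, ] < p_max
    if (!any(ok)) return(NULL)
    j <- which(ok)[which.max(corr[i, ok])]   # ties: earliest stage wins
    data.frame(module = mods[i], stage = colnames(corr)[j],
               correlation = corr[i, j], p_value = pvals[i, j],
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1L))
  map <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(module = character(0), stage = character(0),
               correlation = numeric(0), p_value = numeric(0))
  rownames(map) <- NULL
  list(map = map, unassigned = mods[!keep])
}

#' Merge same-stage modules into stage gene sets
#'
#' Unions the member genes of all modules assigned to each stage. Stages
#' without a module are retained with an empty set. Module disjointness
#' makes the stage sets pairwise disjoint.
#'
#' @param map Assignment data frame from \code{\link{assign_modules}} (the
#'   \code{$map} element).
#' @param assignment Named integer vector gene -> module label.
#' @param stage_order Stages to report, in order.
#' @return List with \code{sets} (stage -> character vector of gene ids) and
#'   \code{provenance} (stage -> contributing module labels).
#' @export
build_stage_gene_sets <- function(map, assignment,
                                  stage_order = ped_stages()) {
  sets <- stats::setNames(vector("list", length(stage_order)), stage_order)
  prov <- stats::setNames(vector("list", length(stage_order)), stage_order)
  for (s in stage_order) {
    mods <- map$module[map$stage == s]
    prov[[s]] <- mods
    sets[[s]] <- if (length(mods))
      names(assignment)[assignment %in% as.integer(mods)] else character(0)
  }
  list(sets = sets, provenance = prov)
}

#' Hub genes of a module
#'
#' Genes whose expression profile has signed Pearson correlation with the
#' module eigengene above \code{r_min} at p below \code{p_max}.
#' Anti-correlated genes are not hubs.
#'
#' @param x Numeric matrix, genes x samples, on the fitting scale.
#' @param eigengene Numeric vector over samples.
#' @param r_min Correlation threshold (strict).
#' @param p_max P-value threshold (strict).
#' @return Character vector of hub gene ids.
#' @export
hub_genes <- function(x, eigengene, r_min = 0.9, p_max = 0.01) {
  v <- apply(x, 1L, stats::var)
  x <- x[v > 0, , drop = FALSE]
  r <- drop(stats::cor(t(x), eigengene))
  p <- cor_pvalue(r, ncol(x))
  rownames(x)[r > r_min & p < p_max]
}
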