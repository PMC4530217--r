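#' Canonical preimplantation stage order
#'
#' Developmental order of the seven human preimplantation stages handled by
#' this package: oocyte, zygote, 2-cell, 4-cell, 8-cell, morulae and late
#' blastocyst.
#'
#' @return Character vector of stage labels in developmental order.
#' @export
#' @examples
#' ped_stages()
ped_stages <- function() {
  c("oocyte", "zygote", "2cell", "4cell", "8cell", "morulae", "late_blastocyst")
}

#' Construct an expression set
#'
#' Container for a genes x samples matrix of nonnegative expression values
#' (RPKM scale) together with a sample -> developmental stage mapping.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All values must be finite and >= 0.
#' @param sample_stage Named character vector mapping sample id -> stage
#'   label. Every sample in \code{values} must be covered and every stage
#'   present must have at least 2 samples.
#' @return An object of class \code{"expression_set"}: a list with elements
#'   \code{values} and \code{stage}.
#' @export
expression_set <- function(values, sample_stage) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene ids as rownames and sample ids as colnames")
  stage <- sample_stage[colnames(values)]
  names(stage) <- colnames(values)
  es <- structure(list(values = values, stage = stage), class = "expression_set")
  validate_expression_set(es)
  es
}

validate_expression_set <- function(es) {
  v <- es$values
  dup <- rownames(v)[duplicated(rownames(v))]
  if (length(dup))
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(v)[duplicated(colnames(v))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(v)))
    stop("expression values must be finite")
  if (any(v < 0))
    stop("expression values must be nonnegative")
  miss <- colnames(v)[is.na(es$stage)]
  if (length(miss))
    stop("missing stage label for sample(s): ", paste(miss, collapse = ", "))
  tab <- table(es$stage)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("stage(s) with fewer than 2 samples: ", paste(small, collapse = ", "))
  invisible(es)
}

#' Load an RPKM table with a stage sidecar
#'
#' Reads a tab-separated expression table (first column gene id, remaining
#' columns one per sample, header row of sample ids) and a two-column
#' tab-separated sidecar mapping \code{sample_id} to \code{stage}.
#'
#' Rows containing non-numeric cells are rejected with a warning naming the
#' genes; a duplicated gene id or a sample without a stage label is an error.
#'
#' @param path Path to the expression TSV.
#' @param stage_path Path to the two-column (sample_id, stage) TSV.
#' @return An \code{\link{expression_set}}.
#' @export
load_rpkm_table <- function(path, stage_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("expression table needs a gene id column and >= 1 sample")
  ids <- tab[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  num <- suppressWarnings(
    vapply(tab[-1L], function(col) as.numeric(col), numeric(nrow(tab))))
  if (nrow(tab) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(tab)[-1L]))
  bad <- apply(num, 1L, function(r) any(is.na(r)))
  if (any(bad)) {
    warning("rejected ", sum(bad), " row(s) with non-numeric cells: ",
            paste(ids[bad], collapse = ", "))
    num <- num[!bad, , drop = FALSE]
    ids <- ids[!bad]
  }
  rownames(num) <- ids
  st <- utils::read.delim(stage_path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (ncol(st) < 2L) stop("stage table must have columns sample_id, stage")
  stage <- st[[2L]]
  names(stage) <- st[[1L]]
  expression_set(num, stage)
}

#' Write an expression set back to TSV
#'
#' Inverse of \code{\link{load_rpkm_table}}: writes the expression matrix and
#' the (sample_id, stage) sidecar in the same dialect, with full double
#' precision so that load/write round-trips are bit-for-bit exact.
#'
#' @param es An \code{\link{expression_set}}.
#' @param path Output path for the expression TSV.
#' @param stage_path Output path for the stage sidecar TSV.
#' @return Invisibly, \code{c(path, stage_path)}.
#' @export
write_rpkm_table <- function(es, path, stage_path) {
  v <- es$values
  txt <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], formatC(v[i, ], format = "g", digits = 17)),
          collapse = "\t"), character(1L))
  writeLines(c(paste(c("gene_id", colnames(v)), collapse = "\t"), txt), path)
  utils::write.table(
    data.frame(sample_id = colnames(v), stage = unname(es$stage)),
    stage_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, stage_path))
}

#' Remove genes with low average expression
#'
#' Drops genes whose mean expression across all samples falls below
#' \code{min_mean} (default 0.5 RPKM), the filter applied to the embryo
#' profiles before network construction. Gene order among survivors is
#' preserved.
#'
#' @param es An \code{\link{expression_set}}.
#' @param min_mean Minimum across-sample mean to retain a gene.
#' @return A filtered \code{expression_set}.
#' @export
filter_low_expression <- function(es, min_mean = 0.5) {
  keep <- rowMeans(es$values) >= min_mean
  if (!any(keep))
    stop("all ", length(keep), " genes fall below mean expression ", min_mean)
  expression_set(es$values[keep, , drop = FALSE], es$stage)
}

#' Re-key genes through an identifier mapping
#'
#' Maps row identifiers (e.g. gene symbols) to stable gene ids, dropping
#' genes without a mapping entry. When two source symbols map to the same
#' target id, the row with the higher mean expression is kept (the better
#' measured transcript).
#'
#' @param es An \code{\link{expression_set}}.
#' @param mapping Named character vector (names = source ids, values =
#'   target ids) or a two-column data frame (source, target).
#' @return An \code{expression_set} keyed by the mapped ids.
#' @export
map_gene_ids <- function(es, mapping) {
  if (is.data.frame(mapping)) {
    m <- as.character(mapping[[2L]])
    names(m) <- as.character(mapping[[1L]])
    mapping <- m
  }
  if (length(mapping) == 0L) stop("empty id mapping")
  if (anyDuplicated(names(mapping)))
    stop("id mapping is not single-valued per source symbol")
  tgt <- unname(mapping[rownames(es$values)])
  keep <- !is.na(tgt)
  if (!any(keep)) stop("no gene survived the id mapping")
  v <- es$values[keep, , drop = FALSE]
  tgt <- tgt[keep]
  # resolve collisions: keep the higher-mean row per target id (earlier row on ties)
  mu <- rowMeans(v)
  ord <- order(tgt, -mu, seq_along(tgt))
  sel <- sort(ord[!duplicated(tgt[ord])])
  v <- v[sel, , drop = FALSE]
  rownames(v) <- tgt[sel]
  expression_set(v, es$stage)
}

quantile_normalize_matrix <- function(x) {
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    sorted <- x[o, j]
    grp <- cumsum(c(TRUE, diff(sorted) != 0))       # tied spans share a group
    gm <- vapply(split(ref, grp), mean, numeric(1L))
    out[o, j] <- gm[grp]
  }
  out
}

#' Quantile-normalize samples
#'
#' Forces every sample onto a common distribution: the across-sample mean of
#' sorted value vectors. Ties within a sample receive the mean of the
#' reference values over their rank span. Idempotent (up to floating point)
#' and requires at least two samples.
#'
#' @param es An \code{\link{expression_set}} or a plain numeric matrix
#'   (genes x samples).
#' @return Object of the same kind as the input, normalized.
#' @export
quantile_normalize <- function(es) {
  if (is.matrix(es)) {
    if (ncol(es) < 2L) stop("quantile normalization needs >= 2 samples")
    return(quantile_normalize_matrix(es))
  }
  if (ncol(es$values) < 2L) stop("quantile normalization needs >= 2 samples")
  expression_set(quantile_normalize_matrix(es$values), es$stage)
}

#' @export
print.expression_set <- function(x, ...) {
  tab <- table(factor(x$stage, levels = unique(x$stage)))
  cat("expression_set: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("stages: ", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
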