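#' Gene-age intervals in lineage order
#'
#' The four phylostratigraphic intervals used to bin gene roots, from oldest
#' to youngest.
#'
#' @return Character vector of interval names.
#' @export
age_intervals <- function() {
  c("Opisthokonta-Bilateria", "Chordata-Euteleostomi",
    "Sarcopterygii-Amniota", "Mammalia-Eutheria")
}

# taxon ladder: every taxon on the Opisthokonta..human lineage maps to its
# bounding interval; taxa younger than Eutheria are excluded (too few genes
# for a stable test)
.age_ladder <- local({
  map <- c(
    Opisthokonta = "Opisthokonta-Bilateria",
    Eumetazoa    = "Opisthokonta-Bilateria",
    Bilateria    = "Opisthokonta-Bilateria",
    Chordata     = "Chordata-Euteleostomi",
    Vertebrata   = "Chordata-Euteleostomi",
    Euteleostomi = "Chordata-Euteleostomi",
    Sarcopterygii = "Sarcopterygii-Amniota",
    Tetrapoda    = "Sarcopterygii-Amniota",
    Amniota      = "Sarcopterygii-Amniota",
    Mammalia     = "Mammalia-Eutheria",
    Theria       = "Mammalia-Eutheria",
    Eutheria     = "Mammalia-Eutheria")
  young <- c("Boreoeutheria", "Euarchontoglires", "Primates", "Haplorrhini",
             "Simiiformes", "Catarrhini", "Hominoidea", "Hominidae",
             "Homininae", "Homo sapiens")
  map[young] <- NA_character_
  map
})

#' Classify a gene's phylogenetic root into an age interval
#'
#' Maps the root taxon of a gene tree (its oldest node on the
#' Opisthokonta..human lineage) to one of the four age intervals of
#' \code{\link{age_intervals}}. Taxa younger than Eutheria return \code{NA}
#' (excluded: too few genes there to test); an unknown taxon is an error.
#'
#' @param root_taxon Character vector of root taxon names.
#' @return Character vector of interval names, \code{NA} for excluded taxa.
#' @export
#' @examples
#' classify_gene_age(c("Bilateria", "Chordata", "Homo sapiens"))
classify_gene_age <- function(root_taxon) {
  unknown <- setdiff(unique(root_taxon), names(.age_ladder))
  if (length(unknown))
    stop("unknown root taxon(s): ", paste(unknown, collapse = ", "))
  unname(.age_ladder[root_taxon])
}

#' Load per-gene dN/dS values
#'
#' Reads a TSV with columns \code{gene_id}, \code{dn}, \code{ds} (or
#' \code{gene_id}, \code{dnds} precomputed) and returns the dN/dS ratio per
#' gene. Genes with ds = 0 or missing values get \code{NA}; genes outside
#' \code{universe} (the expression matrix) are dropped. A skip report is
#' attached as attributes \code{n_ds_zero}, \code{n_missing},
#' \code{n_outside}.
#'
#' @param path Path to the TSV.
#' @param universe Character vector of gene ids present in the expression
#'   matrix; \code{NULL} keeps all.
#' @return Named numeric vector of dN/dS ratios.
#' @export
load_dnds <- function(path, universe = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stop("dN/dS table needs a gene_id column")
  if (all(c("dn", "ds") %in% names(tab))) {
    if (any(tab$dn < 0, na.rm = TRUE) || any(tab$ds < 0, na.rm = TRUE))
      stop("negative dn or ds value")
    zero <- !is.na(tab$ds) & tab$ds == 0
    miss <- is.na(tab$dn) | is.na(tab$ds)
    ratio <- ifelse(zero | miss, NA_real_, tab$dn / tab$ds)
  } else if ("dnds" %in% names(tab)) {
    if (any(tab$dnds < 0, na.rm = TRUE)) stop("negative dN/dS value")
    zero <- rep(FALSE, nrow(tab))
    miss <- is.na(tab$dnds)
    ratio <- tab$dnds
  } else stop("dN/dS table needs dn+ds or dnds columns")
  names(ratio) <- tab$gene_id
  outside <- 0L
  if (!is.null(universe)) {
    keep <- names(ratio) %in% universe
    outside <- sum(!keep)
    ratio <- ratio[keep]
  }
  structure(ratio, n_ds_zero = sum(zero), n_missing = sum(miss & !zero),
            n_outside = outside)
}

# connected components of a bipartite edge list via union-find
.bipartite_components <- function(a, b) {
  nodes <- c(paste0("A:", a), paste0("B:", b))
  ids <- unique(nodes)
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- match(paste0("A:", a), ids)
  ib <- match(paste0("B:", b), ids)
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_along(ids), find, integer(1L))
  names(comp) <- ids
  comp
}

#' Classify human genes by zebrafish orthology state
#'
#' Given human-zebrafish homology pairs, classifies each human gene in the
#' universe by the shape of the connected component it belongs to in the
#' bipartite homology graph: a 1-1 component is \code{one2one}; a component
#' duplicated on exactly one side is \code{one2many}; duplications on both
#' sides give \code{many2many}; genes without any pair are \code{new_gene}
#' (no ortholog in zebrafish). Self-pairs and duplicate rows are removed
#' with a warning.
#'
#' @param pairs Data frame with columns \code{human_gene},
#'   \code{zebrafish_gene} (first two columns used).
#' @param universe Character vector of human gene ids to classify.
#' @return Named character vector over \code{universe} with values
#'   \code{one2one}, \code{one2many}, \code{many2many}, \code{new_gene}.
#' @export
classify_orthologs <- function(pairs, universe) {
  h <- as.character(pairs[[1L]])
  z <- as.character(pairs[[2L]])
  bad <- h == z | duplicated(paste(h, z, sep = "\r"))
  if (any(bad)) {
    warning("removed ", sum(bad), " self or duplicate homology pair(s)")
    h <- h[!bad]; z <- z[!bad]
  }
  cls <- stats::setNames(rep("new_gene", length(universe)), universe)
  if (!length(h)) return(cls)
  comp <- .bipartite_components(h, z)
  nh <- table(comp[unique(paste0("A:", h))])
  nz <- table(comp[unique(paste0("B:", z))])
  for (g in intersect(unique(h), universe)) {
    cid <- as.character(comp[paste0("A:", g)])
    ch <- nh[cid]; cz <- nz[cid]
    cls[g] <- if (ch == 1L && cz == 1L) "one2one"
      else if (ch > 1L && cz > 1L) "many2many"
      else "one2many"
  }
  cls
}

#' Flag transcription factors from GO annotations
#'
#' A gene is a TF iff it carries GO:0006355 (regulation of transcription,
#' DNA-dependent).
#'
#' @param go_annotations Data frame with columns \code{gene_id},
#'   \code{go_id} (long format, one row per annotation).
#' @param universe Character vector of gene ids to flag.
#' @return Named logical vector over \code{universe}.
#' @export
flag_tfs <- function(go_annotations, universe) {
  tf_genes <- unique(go_annotations$gene_id[go_annotations$go_id == "GO:0006355"])
  stats::setNames(universe %in% tf_genes, universe)
}

#' Flag genes with an HCNE in the proximal promoter
#'
#' Tests, per gene, whether any highly conserved noncoding element overlaps
#' the \code{window} base pairs upstream of the transcription start site.
#' Coordinates are 0-based half-open; for a + strand gene the window is
#' [tss - window, tss), for a - strand gene [tss, tss + window). Windows
#' extending below 0 are clipped. Overlap is half-open: start < window end
#' and end > window start, on the same chromosome.
#'
#' @param loci Data frame with columns \code{gene_id}, \code{chrom},
#'   \code{tss}, \code{strand}.
#' @param hcnes Data frame with columns \code{chrom}, \code{start},
#'   \code{end} (and optionally \code{identity}, required >= 90).
#' @param window Upstream window size in base pairs.
#' @return Named logical vector over the loci's gene ids.
#' @export
flag_hcne <- function(loci, hcnes, window = 500L) {
  if ("identity" %in% names(hcnes) && any(hcnes$identity < 90))
    stop("HCNE input contract violated: identity below 90%")
  if (any(hcnes$start >= hcnes$end)) stop("HCNE intervals must have start < end")
  if (!all(loci$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  w_start <- ifelse(loci$strand == "+", pmax(loci$tss - window, 0L), loci$tss)
  w_end <- ifelse(loci$strand == "+", loci$tss, loci$tss + window)
  out <- logical(nrow(loci))
  for (ch in unique(loci$chrom)) {
    li <- which(loci$chrom == ch)
    hs <- hcnes[hcnes$chrom == ch, , drop = FALSE]
    if (!nrow(hs)) next
    out[li] <- vapply(li, function(i)
      any(hs$start < w_end[i] & hs$end > w_start[i]), logical(1L))
  }
  stats::setNames(out, loci$gene_id)
}

#' Assemble the per-gene annotation table
#'
#' Collects the five evolutionary annotations into one data frame keyed by
#' gene id: dN/dS ratio, age interval, zebrafish ortholog class, TF flag and
#' promoter-HCNE flag. Genes missing from an input get \code{NA} for that
#' column (and are excluded from that analysis's background downstream).
#'
#' @param universe Character vector of gene ids (the expression matrix rows).
#' @param dnds Named numeric vector (from \code{\link{load_dnds}}).
#' @param age_interval Named character vector of age intervals.
#' @param ortholog_class Named character vector (from
#'   \code{\link{classify_orthologs}}).
#' @param is_tf,has_hcne Named logical vectors.
#' @return Data frame with rownames = \code{universe} and columns
#'   \code{dnds}, \code{age_interval}, \code{ortholog_class}, \code{is_tf},
#'   \code{has_hcne}.
#' @export
gene_annotation_table <- function(universe, dnds = NULL, age_interval = NULL,
                                  ortholog_class = NULL, is_tf = NULL,
                                  has_hcne = NULL) {
  pick <- function(v, default = NA) {
    if (is.null(v)) rep(default, length(universe)) else unname(v[universe])
  }
  out <- data.frame(
    dnds = pick(dnds, NA_real_),
    age_interval = pick(age_interval, NA_character_),
    ortholog_class = pick(ortholog_class, NA_character_),
    is_tf = pick(is_tf),
    has_hcne = pick(has_hcne),
    row.names = universe, stringsAsFactors = FALSE)
  if (any(out$dnds < 0, na.rm = TRUE)) stop("negative dN/dS ratio")
  out
}
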