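# small in-code fixtures shared across test files

# expression set with explicit values; samples default to two stages
tiny_es <- function(values, stages = NULL) {
  n <- ncol(values)
  if (is.null(stages))
    stages <- if (n < 4) rep("oocyte", n)
      else rep(c("oocyte", "zygote"), c(ceiling(n / 2), floor(n / 2)))
  names(stages) <- colnames(values)
  expression_set(values, stages)
}

# random RPKM-scale matrix with gene/sample names
random_rpkm <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_genes * n_samples, 3, 1), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# random symmetric adjacency with unit diagonal
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

# brute-force TOM by triple loop (independent oracle)
tom_brute_force <- function(a) {
  n <- nrow(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(out) <- dimnames(a)
  out
}

# expression matrix with planted blocks: each block overexpressed in one
# stage of a 7-stage 3,3,4,4,4,4,4 design (log2-space model)
planted_blocks <- function(n_per_block, stages_hit, n_noise = 0, delta = 3,
                           noise_sd = 0.4, seed = 1) {
  set.seed(seed)
  sts <- ped_stages()
  reps <- c(3, 3, 4, 4, 4, 4, 4)
  sample_stage <- rep(sts, reps)
  names(sample_stage) <- paste0(sample_stage, "_",
                                unlist(lapply(reps, seq_len)))
  n <- n_per_block * length(stages_hit) + n_noise
  lab <- c(rep(seq_along(stages_hit), each = n_per_block),
           rep(0L, n_noise))
  b <- rnorm(n, 3, 1)
  x <- b + matrix(rnorm(n * length(sample_stage), 0, noise_sd), n)
  for (k in seq_along(stages_hit))
    x[lab == k, sample_stage == stages_hit[k]] <-
      x[lab == k, sample_stage == stages_hit[k]] + delta
  rpkm <- pmax(2^x - 1, 0)
  dimnames(rpkm) <- list(sprintf("g%04d", seq_len(n)), names(sample_stage))
  list(es = expression_set(rpkm, sample_stage), truth = lab)
}

# annotation table with constant flags, handy for enrichment tests
flat_annot <- function(ids, dnds = NULL, age = NULL, ortho = NULL,
                       tf = NULL, hcne = NULL) {
  gene_annotation_table(
    ids,
    dnds = if (!is.null(dnds)) setNames(dnds, ids),
    age_interval = if (!is.null(age)) setNames(age, ids),
    ortholog_class = if (!is.null(ortho)) setNames(ortho, ids),
    is_tf = if (!is.null(tf)) setNames(tf, ids),
    has_hcne = if (!is.null(hcne)) setNames(hcne, ids))
}

# adjusted Rand index (Hubert & Arabie) -- closed form over the
# contingency table; used as planted-recovery score
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
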