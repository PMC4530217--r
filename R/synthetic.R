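#' Synthetic-data configuration
#'
#' Parameters of the seeded generator that emulates a replicate-structured
#' preimplantation RPKM matrix with planted stage-specific overexpression
#' modules, plus per-gene annotation tables with planted per-stage
#' conservation signatures.
#'
#' The expression model is log2-space additive:
#' \deqn{x_{gs} = b_g + \delta \, 1[g \in \textrm{module of stage}(s)] +
#'   \epsilon_{gs}},
#' with baseline \eqn{b_g \sim N(baseline\_mean, baseline\_sd^2)}, noise
#' \eqn{\epsilon \sim N(0, noise\_sd^2)}, and emitted RPKM
#' \eqn{\max(2^x - 1, 0)}. Annotations are drawn per gene from the stage's
#' (or the background's) conservation plan: dN/dS ~ LogNormal(dnds_logmean,
#' dnds_sdlog), age interval ~ Categorical(age_probs), ortholog class ~
#' Categorical(ortholog_probs), TF and HCNE flags ~ Bernoulli.
#'
#' @param n_genes Total gene count (module demand must fit).
#' @param stage_plan Data frame (stage, n) of replicate counts; default the
#'   design 3,3,4,4,4,4,4 over the seven stages.
#' @param modules_per_stage Planted modules per stage.
#' @param module_size Genes per planted module.
#' @param effect_size Log2 up-shift delta in the module's target stage.
#' @param noise_sd Log2-space noise standard deviation.
#' @param baseline_mean,baseline_sd Log2-space baseline distribution.
#' @param dnds_sdlog Log-sd of the per-gene dN/dS draw.
#' @param conservation_plan Named list: one entry per stage plus
#'   \code{background}, each a list with \code{dnds_logmean},
#'   \code{age_probs} (4, order of \code{\link{age_intervals}}),
#'   \code{ortholog_probs} (one2one, one2many, many2many, new_gene),
#'   \code{tf_rate}, \code{hcne_rate}.
#' @param seed Integer seed; all generator draws are derived from it.
#' @return Object of class \code{"synthetic_config"}.
#' @seealso \code{\link{ped_preset}} for the ready-made preimplantation
#'   preset.
#' @export
synthetic_config <- function(n_genes = 1200L,
                             stage_plan = data.frame(
                               stage = ped_stages(),
                               n = c(3L, 3L, 4L, 4L, 4L, 4L, 4L)),
                             modules_per_stage = 1L,
                             module_size = 50L,
                             effect_size = 3,
                             noise_sd = 0.4,
                             baseline_mean = 3,
                             baseline_sd = 1,
                             dnds_sdlog = 0.4,
                             conservation_plan = NULL,
                             seed = 1L) {
  if (effect_size <= 0) stop("'effect_size' must be > 0")
  stages <- stage_plan$stage
  if (is.null(conservation_plan)) {
    bgp <- list(dnds_logmean = -1.7,
                age_probs = c(0.55, 0.20, 0.10, 0.15),
                ortholog_probs = c(0.565, 0.233, 0.051, 0.151),
                tf_rate = 0.11, hcne_rate = 0.066)
    conservation_plan <- c(stats::setNames(rep(list(bgp), length(stages)),
                                           stages),
                           list(background = bgp))
  }
  for (p in conservation_plan) {
    if (abs(sum(p$age_probs) - 1) > 1e-8 ||
        abs(sum(p$ortholog_probs) - 1) > 1e-8)
      stop("probability vectors in conservation_plan must sum to 1")
  }
  need <- length(stages) * modules_per_stage * module_size
  if (need > n_genes)
    stop("module demand (", need, " genes) exceeds n_genes (", n_genes, ")")
  structure(list(n_genes = as.integer(n_genes), stage_plan = stage_plan,
                 modules_per_stage = as.integer(modules_per_stage),
                 module_size = as.integer(module_size),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 dnds_sdlog = dnds_sdlog,
                 conservation_plan = conservation_plan,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Preimplantation-embryo preset
#'
#' The generator configuration used as the package's reference study
#' condition: seven stages with replicate counts 3,3,4,4,4,4,4; one planted
#' 50-gene module per stage (log2 effect 3, noise sd 0.4, within-module
#' correlation around 0.88); and a conservation plan carrying the
#' qualitative early-embryo signals -- per-stage dN/dS log-medians
#' (-1.2, -1.5, -1.8, -2.1, -1.5, -1.8, -2.1) so the conservation score
#' traces up-down-up across development, an 8-cell stage rich in
#' recently born (Mammalia-Eutheria) genes and zebrafish new_genes, a late
#' blastocyst rich in ancient (Opisthokonta-Bilateria) genes and one2one
#' orthologs, a 4-cell excess of one2many orthologs, and TF/HCNE excess
#' through the genome-activation stages (2-cell to morulae).
#'
#' @param n_genes Total gene count (default 1200; 350 module genes + noise).
#' @param seed Integer seed.
#' @return A \code{\link{synthetic_config}}.
#' @export
ped_preset <- function(n_genes = 1200L, seed = 1L) {
  bg_age <- c(0.55, 0.20, 0.10, 0.15)          # OpB, ChE, SaA, MaE
  bg_ort <- c(0.565, 0.233, 0.051, 0.151)      # o2o, o2m, m2m, new
  plan <- list(
    oocyte = list(dnds_logmean = -1.2, age_probs = bg_age,
                  ortholog_probs = bg_ort, tf_rate = 0.11, hcne_rate = 0.066),
    zygote = list(dnds_logmean = -1.5, age_probs = bg_age,
                  ortholog_probs = bg_ort, tf_rate = 0.11, hcne_rate = 0.066),
    `2cell` = list(dnds_logmean = -1.8, age_probs = bg_age,
                   ortholog_probs = bg_ort, tf_rate = 0.30, hcne_rate = 0.30),
    `4cell` = list(dnds_logmean = -2.1, age_probs = bg_age,
                   ortholog_probs = c(0.40, 0.47, 0.05, 0.08),
                   tf_rate = 0.30, hcne_rate = 0.066),
    `8cell` = list(dnds_logmean = -1.5,
                   age_probs = c(0.25, 0.15, 0.10, 0.50),
                   ortholog_probs = c(0.20, 0.20, 0.05, 0.55),
                   tf_rate = 0.30, hcne_rate = 0.066),
    morulae = list(dnds_logmean = -1.8, age_probs = bg_age,
                   ortholog_probs = bg_ort, tf_rate = 0.30, hcne_rate = 0.066),
    late_blastocyst = list(dnds_logmean = -2.1,
                           age_probs = c(0.92, 0.03, 0.02, 0.03),
                           ortholog_probs = c(0.94, 0.04, 0.01, 0.01),
                           tf_rate = 0.06, hcne_rate = 0.04),
    background = list(dnds_logmean = -1.7, age_probs = bg_age,
                      ortholog_probs = bg_ort, tf_rate = 0.11,
                      hcne_rate = 0.066))
  synthetic_config(n_genes = n_genes, conservation_plan = plan, seed = seed)
}

#' Generate a synthetic expression set with planted modules
#'
#' Draws the log2-space model of \code{\link{synthetic_config}} and returns
#' the RPKM-scale expression set plus the planted ground truth. Fully
#' determined by \code{cfg$seed}; draw order is baselines (gene order), then
#' the noise matrix (column-major).
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @return List with \code{es} (an \code{\link{expression_set}}) and
#'   \code{truth} (data frame gene_id, module, stage; module 0 / stage NA
#'   for background genes).
#' @export
generate_expression <- function(cfg) {
  set.seed(cfg$seed)
  stages <- cfg$stage_plan$stage
  reps <- cfg$stage_plan$n
  sample_stage <- rep(stages, reps)
  sample_ids <- unlist(lapply(seq_along(stages), function(i)
    paste0(stages[i], "_", seq_len(reps[i]))))
  names(sample_stage) <- sample_ids
  n <- cfg$n_genes
  ids <- sprintf("G%05d", seq_len(n))
  n_mod <- length(stages) * cfg$modules_per_stage
  module <- rep(0L, n)
  stage_of <- rep(NA_character_, n)
  for (m in seq_len(n_mod)) {
    idx <- ((m - 1L) * cfg$module_size + 1L):(m * cfg$module_size)
    module[idx] <- m
    stage_of[idx] <- stages[((m - 1L) %% length(stages)) + 1L]
  }
  b <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  eps <- matrix(stats::rnorm(n * length(sample_ids), 0, cfg$noise_sd),
                nrow = n)
  shift <- outer(stage_of, unname(sample_stage),
                 function(g, s) as.numeric(!is.na(g) & g == s))
  x <- b + cfg$effect_size * shift + eps
  rpkm <- pmax(2^x - 1, 0)
  dimnames(rpkm) <- list(ids, sample_ids)
  list(es = expression_set(rpkm, sample_stage),
       truth = data.frame(gene_id = ids, module = module, stage = stage_of,
                          stringsAsFactors = FALSE))
}

# categorical draw per gene from a row-wise probability matrix
.draw_categorical <- function(prob_matrix, levels) {
  cum <- t(apply(prob_matrix, 1L, cumsum))
  u <- stats::runif(nrow(prob_matrix))
  idx <- rowSums(u > cum) + 1L
  levels[pmin(idx, length(levels))]
}

.plan_field <- function(cfg, stage_of, field) {
  plan <- cfg$conservation_plan
  vals <- lapply(ifelse(is.na(stage_of), "background", stage_of),
                 function(s) plan[[s]][[field]])
  do.call(rbind, vals)
}

#' Generate annotation tables consistent with a planted truth
#'
#' Draws per-gene conservation annotations from the stage plans of
#' \code{cfg} and emits them in the exact file dialects the loaders consume:
#' a dN/dS table (dn, ds), a root-taxon table, human-zebrafish homology
#' pairs, a long-format GO table (TFs carry GO:0006355), gene loci on one
#' synthetic chromosome with spaced TSSs, and HCNE intervals placed inside
#' the 500 bp upstream window for flagged genes (plus decoys well outside
#' it). Draw order is field by field in gene order: dN/dS ratio, dS, age,
#' root taxon, ortholog class, TF, HCNE, strand, identity.
#'
#' The returned \code{annot} table records the REALIZED annotations: its
#' ortholog classes are recomputed from the emitted homology pairs, so
#' loading the emitted files reproduces it exactly.
#'
#' @param truth Ground-truth data frame from
#'   \code{\link{generate_expression}}.
#' @param cfg The \code{\link{synthetic_config}} used.
#' @param seed Seed for the annotation draws; default \code{cfg$seed + 1}.
#' @return List with \code{annot} (see \code{\link{gene_annotation_table}})
#'   and the emitted tables \code{dnds}, \code{ages}, \code{homology},
#'   \code{go}, \code{loci}, \code{hcne}.
#' @export
generate_annotations <- function(truth, cfg, seed = cfg$seed + 1L) {
  set.seed(seed)
  ids <- truth$gene_id
  n <- length(ids)
  stage_of <- truth$stage

  mu <- vapply(ifelse(is.na(stage_of), "background", stage_of),
               function(s) cfg$conservation_plan[[s]]$dnds_logmean,
               numeric(1L))
  ratio <- stats::rlnorm(n, mu, cfg$dnds_sdlog)
  ds <- stats::runif(n, 0.5, 3)
  dnds_tab <- data.frame(gene_id = ids, dn = ratio * ds, ds = ds,
                         stringsAsFactors = FALSE)

  age <- .draw_categorical(.plan_field(cfg, stage_of, "age_probs"),
                           age_intervals())
  taxa <- list(
    `Opisthokonta-Bilateria` = c("Opisthokonta", "Eumetazoa", "Bilateria"),
    `Chordata-Euteleostomi` = c("Chordata", "Vertebrata", "Euteleostomi"),
    `Sarcopterygii-Amniota` = c("Sarcopterygii", "Tetrapoda", "Amniota"),
    `Mammalia-Eutheria` = c("Mammalia", "Theria", "Eutheria"))
  root <- vapply(age, function(a)
    taxa[[a]][sample.int(3L, 1L)], character(1L))
  ages_tab <- data.frame(gene_id = ids, root_taxon = root,
                         stringsAsFactors = FALSE)

  ocls <- .draw_categorical(.plan_field(cfg, stage_of, "ortholog_probs"),
                            c("one2one", "one2many", "many2many", "new_gene"))
  hp <- list()
  zi <- 0L
  zid <- function(k) sprintf("Z%05d", k)
  for (g in ids[ocls == "one2one"]) {
    zi <- zi + 1L
    hp[[length(hp) + 1L]] <- data.frame(human_gene = g,
                                        zebrafish_gene = zid(zi))
  }
  for (g in ids[ocls == "one2many"]) {
    hp[[length(hp) + 1L]] <- data.frame(human_gene = g,
                                        zebrafish_gene = zid(zi + 1:2))
    zi <- zi + 2L
  }
  m2m <- ids[ocls == "many2many"]
  while (length(m2m) >= 2L) {
    grp <- m2m[1:min(if (length(m2m) == 3L) 3L else 2L, length(m2m))]
    m2m <- setdiff(m2m, grp)
    z <- zid(zi + 1:2)
    zi <- zi + 2L
    rows <- data.frame(
      human_gene = c(grp[1L], grp[1L], grp[-1L]),
      zebrafish_gene = c(z[1L], z[2L], rep_len(z, length(grp) - 1L)))
    hp[[length(hp) + 1L]] <- rows
  }
  if (length(m2m) == 1L) {          # a lone draw cannot be many2many
    hp[[length(hp) + 1L]] <- data.frame(human_gene = m2m,
                                        zebrafish_gene = zid(zi + 1:2))
    zi <- zi + 2L
  }
  homology <- if (length(hp)) do.call(rbind, hp) else
    data.frame(human_gene = character(0), zebrafish_gene = character(0))
  realized <- classify_orthologs(homology, ids)

  tf_rate <- vapply(ifelse(is.na(stage_of), "background", stage_of),
                    function(s) cfg$conservation_plan[[s]]$tf_rate,
                    numeric(1L))
  is_tf <- stats::runif(n) < tf_rate
  go <- rbind(
    data.frame(gene_id = ids, go_id = "GO:0008150",
               stringsAsFactors = FALSE),
    data.frame(gene_id = ids[is_tf], go_id = "GO:0006355",
               stringsAsFactors = FALSE))

  hcne_rate <- vapply(ifelse(is.na(stage_of), "background", stage_of),
                      function(s) cfg$conservation_plan[[s]]$hcne_rate,
                      numeric(1L))
  has_hcne <- stats::runif(n) < hcne_rate
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  tss <- 10000L * seq_len(n) + 5000L
  loci <- data.frame(gene_id = ids, chrom = "chrS", tss = tss,
                     strand = strand, stringsAsFactors = FALSE)
  ident <- round(stats::runif(n, 90, 100), 1)
  mk_hcne <- function(i, inside) {
    if (inside) {
      if (strand[i] == "+") c(tss[i] - 300L, tss[i] - 100L)
      else c(tss[i] + 100L, tss[i] + 300L)
    } else {
      if (strand[i] == "+") c(tss[i] - 3000L, tss[i] - 2500L)
      else c(tss[i] + 2500L, tss[i] + 3000L)
    }
  }
  rows <- lapply(seq_len(n), function(i) {
    if (has_hcne[i]) cbind(i, TRUE)
    else if (i %% 20L == 0L) cbind(i, FALSE)   # decoy outside the window
    else NULL
  })
  rows <- do.call(rbind, rows)
  hcne <- if (is.null(rows))
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               name = character(0), identity = numeric(0))
  else {
    se <- t(vapply(seq_len(nrow(rows)),
                   function(r) mk_hcne(rows[r, 1L], as.logical(rows[r, 2L])),
                   integer(2L)))
    data.frame(chrom = "chrS", start = se[, 1L], end = se[, 2L],
               name = paste0("hcne_", seq_len(nrow(rows))),
               identity = ident[rows[, 1L]], stringsAsFactors = FALSE)
  }

  annot <- gene_annotation_table(
    ids,
    dnds = stats::setNames(ratio, ids),
    age_interval = stats::setNames(age, ids),
    ortholog_class = realized,
    is_tf = stats::setNames(is_tf, ids),
    has_hcne = stats::setNames(has_hcne, ids))
  list(annot = annot, dnds = dnds_tab, ages = ages_tab, homology = homology,
       go = go, loci = loci, hcne = hcne)
}

#' Write a loadable fixture directory
#'
#' Generates expression and annotations from \code{cfg} and writes every
#' file in the dialects the loaders consume: \code{expression.tsv},
#' \code{stages.tsv}, \code{dnds.tsv}, \code{gene_ages.tsv},
#' \code{homology.tsv}, \code{go_annotations.tsv}, \code{gene_loci.tsv},
#' \code{hcne.bed} (chrom, start, end, name, identity; no header) and the
#' planted \code{truth.tsv}.
#'
#' @param cfg A \code{\link{synthetic_config}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
simulate_fixture <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2L) != 0L) stop("output directory not writable: ", dir)
  gx <- generate_expression(cfg)
  an <- generate_annotations(gx$truth, cfg)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             stages = file.path(dir, "stages.tsv"),
             dnds = file.path(dir, "dnds.tsv"),
             gene_ages = file.path(dir, "gene_ages.tsv"),
             homology = file.path(dir, "homology.tsv"),
             go_annotations = file.path(dir, "go_annotations.tsv"),
             gene_loci = file.path(dir, "gene_loci.tsv"),
             hcne = file.path(dir, "hcne.bed"),
             truth = file.path(dir, "truth.tsv"))
  write_rpkm_table(gx$es, paths["expression"], paths["stages"])
  wt <- function(df, p, col.names = TRUE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = col.names)
  wt(an$dnds, paths["dnds"])
  wt(an$ages, paths["gene_ages"])
  wt(an$homology, paths["homology"])
  wt(an$go, paths["go_annotations"])
  wt(an$loci, paths["gene_loci"])
  wt(an$hcne, paths["hcne"], col.names = FALSE)
  wt(gx$truth, paths["truth"])
  invisible(paths)
}
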