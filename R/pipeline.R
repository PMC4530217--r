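#' Build a pipeline configuration
#'
#' Assembles input paths and thresholds for \code{\link{run_pipeline}}.
#' \code{dir} is a fixture directory laid out as written by
#' \code{\link{simulate_fixture}}; individual paths can be overridden.
#'
#' @param dir Directory holding the standard input files.
#' @param out_dir Output directory for result tables and the JSON report.
#' @param id_mapping Optional path to a two-column (source, target) TSV of
#'   gene id mappings; \code{NULL} skips the mapping step.
#' @param min_mean Low-expression filter threshold (mean RPKM).
#' @param power,deep_split,min_size,merge_cor,r_min,p_max,hub_r,hub_p,transform
#'   Module-detection parameters, see \code{\link{fit_stage_modules}}.
#' @param n_perm,seed,alternative,alpha_resample,alpha_fisher Conservation
#'   parameters, see \code{\link{stage_conservation}}.
#' @return A named list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(dir, out_dir = file.path(dir, "results"),
                            id_mapping = NULL, min_mean = 0.5, power = 12L,
                            deep_split = 4L, min_size = 30L, merge_cor = 0.9,
                            r_min = 0.7, p_max = 0.01, hub_r = 0.9,
                            hub_p = 0.01, transform = "log2p1",
                            n_perm = 10000L, seed = 1L,
                            alternative = "two.sided", alpha_resample = 0.05,
                            alpha_fisher = 0.01) {
  stopifnot(power >= 1, deep_split %in% 0:4, min_size >= 2,
            merge_cor > 0, merge_cor <= 1, r_min > 0, r_min < 1,
            p_max > 0, p_max <= 1, n_perm >= 1)
  structure(list(
    expression = file.path(dir, "expression.tsv"),
    stages = file.path(dir, "stages.tsv"),
    dnds = file.path(dir, "dnds.tsv"),
    gene_ages = file.path(dir, "gene_ages.tsv"),
    homology = file.path(dir, "homology.tsv"),
    go_annotations = file.path(dir, "go_annotations.tsv"),
    gene_loci = file.path(dir, "gene_loci.tsv"),
    hcne = file.path(dir, "hcne.bed"),
    id_mapping = id_mapping, out_dir = out_dir, min_mean = min_mean,
    power = power, deep_split = deep_split, min_size = min_size,
    merge_cor = merge_cor, r_min = r_min, p_max = p_max, hub_r = hub_r,
    hub_p = hub_p, transform = transform, n_perm = n_perm, seed = seed,
    alternative = alternative, alpha_resample = alpha_resample,
    alpha_fisher = alpha_fisher), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a flat-key YAML file; keys mirror the arguments of
#' \code{\link{pipeline_config}} plus the individual input paths.
#'
#' @param path Path to a YAML file. Must contain at least \code{dir} (or the
#'   individual input paths) and may override any threshold.
#' @return A \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  dir <- if (!is.null(y$dir)) y$dir else dirname(path)
  known <- setdiff(names(formals(pipeline_config)), "dir")
  cfg <- do.call(pipeline_config,
                 c(list(dir = dir), y[intersect(names(y), known)]))
  extra <- setdiff(names(y), c("dir", known))
  for (k in intersect(extra, names(cfg))) cfg[[k]] <- y[[k]]
  cfg
}

#' Run the full analysis pipeline
#'
#' Sequences the entire analysis: load and validate the RPKM matrix; filter
#' low-expression genes; optionally re-key gene ids; quantile-normalize;
#' fit stage-specific coexpression modules; load the five annotations; run
#' the four conservation indices and the trend summary; and write one TSV
#' per result plus \code{report.json} recording every threshold, the seed,
#' input checksums and per-stage counts. Any stage failure aborts with the
#' failing stage named. Outputs are byte-identical across reruns with the
#' same configuration.
#'
#' @param config A \code{"pipeline_config"} (or path to a YAML file for
#'   \code{\link{read_pipeline_config}}).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the fitted \code{stage_modules}, the
#'   \code{stage_conservation} result, the annotation table, and the report
#'   list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- config
  say <- function(...) if (!quiet) message(...)
  step_name <- "setup"
  step <- function(name, expr) {
    step_name <<- name
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    say(sprintf("[%s] done in %.1fs", name,
                proc.time()[["elapsed"]] - t0))
    out
  }
  result <- tryCatch({
    es <- step("expression_io", {
      es <- load_rpkm_table(cfg$expression, cfg$stages)
      es <- filter_low_expression(es, cfg$min_mean)
      if (!is.null(cfg$id_mapping)) {
        m <- utils::read.delim(cfg$id_mapping, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
        es <- map_gene_ids(es, m)
      }
      quantile_normalize(es)
    })
    fit <- step("coexpression", fit_stage_modules(
      es, power = cfg$power, deep_split = cfg$deep_split,
      min_size = cfg$min_size, merge_cor = cfg$merge_cor, r_min = cfg$r_min,
      p_max = cfg$p_max, hub_r = cfg$hub_r, hub_p = cfg$hub_p,
      transform = cfg$transform))
    annot <- step("annotations", {
      universe <- rownames(es$values)
      dnds <- load_dnds(cfg$dnds, universe)
      ages <- utils::read.delim(cfg$gene_ages, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      age <- stats::setNames(classify_gene_age(ages$root_taxon),
                             ages$gene_id)
      hom <- utils::read.delim(cfg$homology, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
      ocls <- classify_orthologs(hom, universe)
      go <- utils::read.delim(cfg$go_annotations, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      loci <- utils::read.delim(cfg$gene_loci, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
      hcne <- utils::read.delim(cfg$hcne, header = FALSE, sep = "\t",
                                stringsAsFactors = FALSE,
                                col.names = c("chrom", "start", "end",
                                              "name", "identity"))
      gene_annotation_table(
        universe, dnds = dnds, age_interval = age, ortholog_class = ocls,
        is_tf = flag_tfs(go, universe),
        has_hcne = flag_hcne(loci, hcne)[universe])
    })
    cons <- step("conservation", stage_conservation(
      fit, annot, n_perm = cfg$n_perm, seed = cfg$seed,
      alternative = cfg$alternative, alpha_resample = cfg$alpha_resample,
      alpha_fisher = cfg$alpha_fisher))
    rep <- step("report", write_pipeline_outputs(cfg, es, fit, annot, cons))
    list(es = es, fit = fit, annot = annot, conservation = cons,
         report = rep)
  }, error = function(e) {
    stop("pipeline failed at stage '", step_name, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

write_pipeline_outputs <- function(cfg, es, fit, annot, cons) {
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(data.frame(gene_id = names(fit$assignment),
                module = unname(fit$assignment)), "modules.tsv")
  me <- fit$eigengenes
  wt(cbind(data.frame(module = rownames(me)), as.data.frame(me)),
     "eigengenes.tsv")
  wt(fit$stage_map, "stage_map.tsv")
  ss <- do.call(rbind, lapply(names(fit$stage_sets), function(s)
    if (length(fit$stage_sets[[s]]))
      data.frame(stage = s, gene_id = fit$stage_sets[[s]]) else NULL))
  if (is.null(ss)) ss <- data.frame(stage = character(0),
                                    gene_id = character(0))
  wt(ss, "stage_sets.tsv")
  hb <- do.call(rbind, lapply(names(fit$hubs), function(m)
    if (length(fit$hubs[[m]]))
      data.frame(module = m, gene_id = fit$hubs[[m]]) else NULL))
  if (is.null(hb)) hb <- data.frame(module = character(0),
                                    gene_id = character(0))
  wt(hb, "hub_genes.tsv")
  wt(cons$dnds, "dnds_test.tsv")
  for (nm in c("age", "ortholog", "tf", "hcne"))
    if (!is.null(cons[[nm]])) wt(cons[[nm]], paste0(nm, "_enrichment.tsv"))
  if (!is.null(cons$trend)) {
    tr <- cons$trend
    wt(data.frame(stage = tr$stage_order,
                  conservation_score = unname(tr$conservation_score),
                  change_from_previous = c(NA, tr$direction_changes)),
       "trend.tsv")
  }
  inputs <- unlist(cfg[c("expression", "stages", "dnds", "gene_ages",
                         "homology", "go_annotations", "gene_loci", "hcne")])
  empty_sets <- names(fit$stage_sets)[
    vapply(fit$stage_sets, length, integer(1L)) == 0L]
  report <- list(
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    input_checksums = as.list(tools::md5sum(inputs)),
    n_genes = nrow(es$values),
    n_samples = ncol(es$values),
    n_modules = nrow(fit$eigengenes),
    n_modules_assigned = nrow(fit$stage_map),
    stage_set_sizes = lapply(fit$stage_sets, length),
    empty_stage_sets = empty_sets,
    trend_pattern = if (!is.null(cons$trend)) cons$trend$pattern_label
      else NA,
    complete = !is.null(cons$trend))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  report
}
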