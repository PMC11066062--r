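#' Pipeline configuration
#'
#' Collects every tunable constant of the workflow with its default:
#' consensus retention fraction 0.10, promoter half-width 2,000 bp,
#' cis window 250,000 bp at Bonferroni alpha 0.01 with 2,500 bp proximal
#' calls, DAR thresholds (adjusted p 0.01, |log2FC| 0.5), and the
#' progression settings (10 folds, 1000 runs, batch minimum 4, IQR
#' multiplier 1.5, 10% test split, majority threshold 0.5).
#'
#' @param out_dir Output directory for stage artifacts.
#' @param master_seed Master seed for all stages.
#' @param ... Overrides for any default listed above (e.g.
#'   `progression = list(n_runs = 100)`), plus an optional `cohort` list
#'   passed to [cohort_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "atacohort_out", master_seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir, master_seed = as.integer(master_seed),
    consensus = list(min_fraction = 0.10),
    promoter_halfwidth = 2000,
    diff = list(adj_p = 0.01, min_abs_lfc = 0.5,
                covariates = c("frip", "sequencer", "sex", "pbmc_type")),
    varpart = list(
      random_covariates = c("diff_batch", "sequencer", "sex", "case_status",
                            "pbmc_type", "ancestry"),
      fixed_covariates = c("frip"), n_regions = 200),
    coexpr = list(window = 250000, alpha = 0.01, proximal = 2500,
                  covariates = c("frip", "sequencer", "case_status", "sex",
                                 "pbmc_type")),
    progression = list(n_folds = 10, n_runs = 1000, min_per_batch = 4,
                       iqr_multiplier = 1.5, test_fraction = 0.1,
                       majority_threshold = 0.5, majority_denominator = "all"),
    qc = list(n_top_pca = 500, n_top_impute = 100, impute_k = 15),
    cohort = list()
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      utils::modifyList(cfg[[nm]], over[[nm]])
    } else over[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

stage_path <- function(cfg, ...) file.path(cfg$out_dir, ...)

require_artifact <- function(cfg, file, producer) {
  p <- stage_path(cfg, file)
  if (!file.exists(p)) {
    abort_validation("missing artifact '%s'; run the '%s' stage first", p, producer)
  }
  p
}

write_tsv <- function(df, path) data.table::fwrite(df, path, sep = "\t")

#' Run one pipeline stage (or the whole chain)
#'
#' Stages: `simulate` (synthetic cohort fixture), `normalize` (size
#' factors, dispersion trend, VST), `varpart`, `diff` (differential
#' accessibility for a chosen contrast), `progression`, `coexpr`, `qc`,
#' and `all` (the full chain). Each stage reads the previous stage's
#' artifacts from `cfg$out_dir`, writes plain-text TSV/JSON outputs, and
#' logs one `key=value` line to stderr.
#'
#' @param stage Stage name.
#' @param cfg A [pipeline_config()].
#' @param contrast Contrast for the `diff` stage (default `"pbmc_type"`).
#' @return Invisibly, the stage's main result object.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "normalize", "varpart",
                                   "diff", "progression", "coexpr", "qc"),
                         cfg = pipeline_config(), contrast = "pbmc_type") {
  stage <- match.arg(stage)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    for (s in c("simulate", "normalize", "varpart", "diff", "progression",
                "coexpr", "qc")) {
      run_pipeline(s, cfg, contrast = contrast)
    }
    return(invisible(NULL))
  }
  t0 <- proc.time()[["elapsed"]]
  res <- switch(
    stage,
    simulate = {
      ccfg <- do.call(cohort_config,
                      utils::modifyList(list(seed = cfg$master_seed), cfg$cohort))
      cohort <- simulate_cohort(ccfg)
      write_cohort(cohort, stage_path(cfg, "cohort"))
      log_line("simulate", seed = cfg$master_seed,
               n_in = 0, n_out = ncol(cohort$counts),
               wall = round(proc.time()[["elapsed"]] - t0, 2))
      cohort
    },
    normalize = {
      counts <- read_counts(require_artifact(cfg, "cohort/counts.tsv", "simulate"))
      nn <- normalize_counts(counts)
      vm <- nn$vst$values
      write_tsv(cbind(data.table::data.table(region_id = rownames(vm)),
                      data.table::as.data.table(vm)),
                stage_path(cfg, "vst.tsv"))
      write_tsv(data.frame(sample_id = names(nn$size_factors),
                           size_factor = nn$size_factors),
                stage_path(cfg, "size_factors.tsv"))
      write_tsv(data.frame(region_id = names(nn$dispersions$mu_hat),
                           mu_hat = nn$dispersions$mu_hat,
                           alpha_hat = nn$dispersions$alpha_hat),
                stage_path(cfg, "dispersions.tsv"))
      jsonlite::write_json(
        list(alpha0 = nn$dispersions$alpha0, a1 = nn$dispersions$a1,
             vst_scale = nn$vst$scale, vst_offset = nn$vst$offset),
        stage_path(cfg, "normalization.json"), auto_unbox = TRUE, digits = NA)
      log_line("normalize", seed = cfg$master_seed, n_in = nrow(counts),
               n_out = nrow(vm),
               wall = round(proc.time()[["elapsed"]] - t0, 2))
      nn
    },
    varpart = {
      vm <- read_vst(cfg)
      md <- read_metadata(cfg)
      ids <- top_variable_regions(vm, min(cfg$varpart$n_regions, nrow(vm)))
      fr <- partition_variance_matrix(vm[ids, , drop = FALSE], md,
                                      cfg$varpart$random_covariates,
                                      cfg$varpart$fixed_covariates)
      write_tsv(fr, stage_path(cfg, "variance_fractions.tsv"))
      write_tsv(summarize_variance_fractions(fr),
                stage_path(cfg, "variance_summary.tsv"))
      log_line("varpart", seed = cfg$master_seed, n_in = length(ids),
               n_out = nrow(fr),
               wall = round(proc.time()[["elapsed"]] - t0, 2))
      fr
    },
    diff = {
      counts <- read_counts(require_artifact(cfg, "cohort/counts.tsv", "simulate"))
      md <- read_metadata(cfg)
      res <- run_differential(counts, md, contrast,
                              covariates = setdiff(cfg$diff$covariates, contrast),
                              adj_p = cfg$diff$adj_p,
                              min_abs_lfc = cfg$diff$min_abs_lfc)
      write_tsv(res, stage_path(cfg, paste0("differential_", contrast, ".tsv")))
      log_line("diff", seed = cfg$master_seed, n_in = nrow(counts),
               n_out = sum(res$is_dar, na.rm = TRUE),
               wall = round(proc.time()[["elapsed"]] - t0, 2))
      res
    },
    progression = {
      vm <- read_vst(cfg)
      md <- read_metadata(cfg)
      regions <- read_regions_bed(require_artifact(cfg, "cohort/regions.bed", "simulate"))
      genes <- read_gene_table(require_artifact(cfg, "cohort/genes.tsv", "simulate"))
      pr <- cfg$progression
      out <- run_progression(vm, regions, genes, md,
                             n_runs = pr$n_runs, master_seed = cfg$master_seed,
                             test_fraction = pr$test_fraction,
                             n_folds = pr$n_folds,
                             min_per_batch = pr$min_per_batch,
                             iqr_multiplier = pr$iqr_multiplier,
                             majority_threshold = pr$majority_threshold,
                             majority_denominator = pr$majority_denominator)
      write_tsv(out$stability$runs[, setdiff(names(out$stability$runs), "selected")],
                stage_path(cfg, "progression_runs.tsv"))
      write_tsv(data.frame(region_id = names(out$stability$selection_frequency),
                           frequency = out$stability$selection_frequency),
                stage_path(cfg, "progression_frequency.tsv"))
      rep <- out$filter_report
      write_tsv(data.frame(
        sample_id = c(rep$excluded_by_correlation, rep$excluded_by_slope_iqr,
                      rep$excluded_by_batch, rep$retained),
        status = c(rep("excluded_by_correlation", length(rep$excluded_by_correlation)),
                   rep("excluded_by_slope_iqr", length(rep$excluded_by_slope_iqr)),
                   rep("excluded_by_batch", length(rep$excluded_by_batch)),
                   rep("retained", length(rep$retained)))),
        stage_path(cfg, "progression_filter_report.tsv"))
      jsonlite::write_json(
        list(majority_set = out$stability$majority_set,
             aggregate = out$stability$aggregate,
             majority_model = out$majority_model[c("train_rmse", "train_r2",
                                                   "test_rmse", "test_r2",
                                                   "test_cor2")]),
        stage_path(cfg, "progression_model.json"), auto_unbox = TRUE, digits = NA)
      log_line("progression", seed = cfg$master_seed,
               n_in = length(rep$retained),
               n_out = length(out$stability$majority_set),
               wall = round(proc.time()[["elapsed"]] - t0, 2))
      out
    },
    coexpr = {
      vm <- read_vst(cfg)
      md <- read_metadata(cfg)
      regions <- read_regions_bed(require_artifact(cfg, "cohort/regions.bed", "simulate"))
      genes <- read_gene_table(require_artifact(cfg, "cohort/genes.tsv", "simulate"))
      expr <- read_expression(cfg)
      cx <- map_all_pairs(expr, vm, genes, regions, md,
                          covariates = cfg$coexpr$covariates,
                          window = cfg$coexpr$window, alpha = cfg$coexpr$alpha,
                          proximal = cfg$coexpr$proximal)
      write_tsv(cx$pairs, stage_path(cfg, "coexpression_pairs.tsv"))
      sm <- cx$summary; sm$peaks_per_gene <- NULL
      jsonlite::write_json(sm, stage_path(cfg, "coexpression_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      log_line("coexpr", seed = cfg$master_seed, n_in = sm$n_pairs_tested,
               n_out = sm$n_significant,
               wall = round(proc.time()[["elapsed"]] - t0, 2))
      cx
    },
    qc = {
      vm <- read_vst(cfg)
      md <- read_metadata(cfg)
      ids <- top_variable_regions(vm, min(cfg$qc$n_top_pca, nrow(vm)))
      pca <- pca_samples(vm, ids)
      write_tsv(data.frame(sample_id = rownames(pca$scores), pca$scores),
                stage_path(cfg, "pca_scores.tsv"))
      rn <- chrx_rnip(md)
      write_tsv(rn$per_sample, stage_path(cfg, "chrx_rnip.tsv"))
      imp <- impute_pbmc_labels(vm, md, k = cfg$qc$impute_k,
                                n_top = cfg$qc$n_top_impute)
      write_tsv(imp[, c("sample_id", "pbmc_type", "pbmc_imputed")],
                stage_path(cfg, "pbmc_imputed.tsv"))
      cl <- inter_sample_correlation_cluster(vm)
      jsonlite::write_json(
        list(rnip_medians = as.list(rn$medians), rnip_mw_p = rn$mw_p_value,
             pca_variance_explained = pca$variance_explained,
             flagged_samples = cl$flagged),
        stage_path(cfg, "qc_summary.json"), auto_unbox = TRUE, digits = NA)
      log_line("qc", seed = cfg$master_seed, n_in = ncol(vm),
               n_out = length(cl$flagged),
               wall = round(proc.time()[["elapsed"]] - t0, 2))
      list(pca = pca, rnip = rn, imputed = imp, clusters = cl)
    }
  )
  invisible(res)
}

read_metadata <- function(cfg) {
  as.data.frame(data.table::fread(
    require_artifact(cfg, "cohort/metadata.tsv", "simulate"), sep = "\t"))
}

read_vst <- function(cfg) {
  dt <- data.table::fread(require_artifact(cfg, "vst.tsv", "normalize"), sep = "\t")
  m <- as.matrix(dt[, -1]); rownames(m) <- dt[[1]]
  m
}

read_expression <- function(cfg) {
  dt <- data.table::fread(
    require_artifact(cfg, "cohort/expression.tsv", "simulate"), sep = "\t")
  m <- as.matrix(dt[, -1]); rownames(m) <- dt[[1]]
  m
}
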