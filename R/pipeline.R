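#' Configuration for a full pipeline run
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [sim_config()]; when given, the cohort is simulated and
#'   written. Otherwise `cells_path`, `clonotypes_path`, `meta_path` and
#'   optionally `flow_path` must point to existing files.
#' @param cells_path,clonotypes_path,meta_path,flow_path Input files used
#'   when `sim` is NULL.
#' @param level Proportion granularity, `"subcluster"` or `"lineage"`.
#' @param exclude Cell labels excluded before proportion computation.
#' @param min_genes,max_pct_mito QC thresholds.
#' @param cutpoint_bounds Quantile bounds of the cutpoint scan.
#' @param min_group_size Minimum group size per side of a cutpoint.
#' @param run_model Fit the leave-one-out risk model (default TRUE).
#' @param nlambda,lambda_min_ratio,inner_folds Penalty-path / inner-CV
#'   parameters of the risk model.
#' @param cutoff_percentile External-style stringent high-risk percentile
#'   reported alongside the median split.
#' @param seed Seed recorded in the manifest and used for model fitting.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, cells_path = NULL,
                       clonotypes_path = NULL, meta_path = NULL,
                       flow_path = NULL, level = "subcluster",
                       exclude = character(), min_genes = 500,
                       max_pct_mito = 10, cutpoint_bounds = c(0.1, 0.9),
                       min_group_size = 5, run_model = TRUE, nlambda = 30,
                       lambda_min_ratio = 0.05, inner_folds = 5,
                       cutoff_percentile = 0.8, seed = 1L) {
  if (is.null(sim) && (is.null(cells_path) || is.null(clonotypes_path) ||
                       is.null(meta_path)))
    stop("either a sim config or input paths must be provided")
  structure(as.list(environment()), class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  clean <- unclass(config)
  clean$out_dir <- NULL   # analysis settings only, not output location
  jsonlite::write_json(clean, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

stage_log <- function(manifest, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste0(..., collapse = ""))
  message(msg)
  manifest$log <- c(manifest$log, msg)
  manifest$stages <- c(manifest$stages, stage)
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (optional), cell QC, per-sample proportions,
#' pre/post group comparisons, B:T/NK lineage ratios, TCR expansion binning,
#' chao1 diversity and expansion comparisons, the optimal-cutpoint forest,
#' and the leave-one-out risk model with occurrence counting, highest-R2
#' selection and median-split stratification. Every stage writes its outputs
#' (CSV/TSV/JSON) under `config$out_dir` before the next stage begins; a
#' failure stops the run with the stage named. A manifest (config hash,
#' package version, per-file checksums, stage log) is written as
#' `manifest.json` and returned.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("immprog")),
                   seed = config$seed, stages = character(0),
                   log = character(0), files = list())
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- inputs ---------------------------------------------------------------
  if (!is.null(config$sim)) {
    cohort <- run_stage("simulate", simulate_cohort(config$sim))
    cells <- cohort$cells; clonotypes <- cohort$clonotypes
    meta <- cohort$meta; flow <- cohort$flow
    write.table(cells, out("cells.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
    write.table(clonotypes, out("clonotypes.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.csv(meta, out("meta.csv"), row.names = FALSE)
    write.csv(flow, out("flow.csv"), row.names = FALSE)
    jsonlite::write_json(list(linear_predictor = as.list(cohort$truth$linear_predictor),
                              group = as.list(cohort$truth$group),
                              interaction_pairs = cohort$truth$interaction_pairs),
                         out("truth.json"), auto_unbox = TRUE, digits = NA)
    manifest <- stage_log(manifest, "simulate",
                          nrow(cells), " cells, ", nrow(clonotypes),
                          " clonotypes, seed ", config$sim$seed)
  } else {
    cells <- run_stage("read", read_cells_tsv(config$cells_path))
    clonotypes <- run_stage("read", read_clonotypes_tsv(config$clonotypes_path))
    meta <- run_stage("read", read_meta_csv(config$meta_path))
    flow <- if (!is.null(config$flow_path))
      run_stage("read", read_flow_csv(config$flow_path)) else NULL
    manifest <- stage_log(manifest, "read", nrow(cells), " cells loaded")
  }

  # -- qc -------------------------------------------------------------------
  cells <- run_stage("qc", suppressMessages(
    qc_filter(cells, config$min_genes, config$max_pct_mito)))
  qlog <- attr(cells, "qc_log")
  manifest <- stage_log(manifest, "qc", "kept ", qlog$n_kept, "/",
                        qlog$n_input, " cells (", qlog$n_low_genes,
                        " low-gene, ", qlog$n_high_mito, " high-mito)")

  # -- proportions ----------------------------------------------------------
  props <- run_stage("proportions",
                     compute_proportions(cells, config$level, config$exclude))
  write_proportions_csv(props, out("proportions.csv"))
  lineage_props <- compute_proportions(cells, "lineage", config$exclude)
  manifest <- stage_log(manifest, "proportions", nrow(props), " samples x ",
                        ncol(props), " cell types")

  # -- comparisons ----------------------------------------------------------
  comps <- run_stage("compare", do.call(rbind, lapply(c("pre", "post"),
    function(tp) {
      cc <- compare_groups(props, meta, timepoint = tp)
      cc$timepoint <- tp
      cc
    })))
  write.csv(comps, out("comparisons.csv"), row.names = FALSE)
  manifest <- stage_log(manifest, "compare", sum(comps$significant),
                        " significant comparisons (joint P/FDR rule)")

  # -- ratios ---------------------------------------------------------------
  tnk <- intersect(c("CD4 T", "CD8 T", "NK"), colnames(lineage_props))
  ratios <- run_stage("ratio",
                      lineage_ratio(lineage_props, "B", tnk))
  write.csv(data.frame(sample_id = names(ratios), b_tnk_ratio = ratios),
            out("ratios.csv"), row.names = FALSE)
  manifest <- stage_log(manifest, "ratio", "B:T/NK ratio for ",
                        length(ratios), " samples")

  # -- flow concordance -----------------------------------------------------
  if (!is.null(flow)) {
    sc_agg <- aggregate_lineages(lineage_props, flow_lineage_groups())
    conc <- run_stage("flow-concordance", flow_concordance(flow, sc_agg))
    write.csv(data.frame(lineage = names(conc), pearson_r = conc),
              out("flow_concordance.csv"), row.names = FALSE)
    manifest <- stage_log(manifest, "flow-concordance", "r = ",
                          paste(signif(conc, 3), collapse = ", "))
  }

  # -- tcr ------------------------------------------------------------------
  clonotypes$expansion <- run_stage("tcr",
    suppressWarnings(classify_expansion(clonotypes$cell_count)))
  write.table(clonotypes, out("expansion.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  div <- diversity_by_sample(clonotypes)
  write.csv(div, out("diversity.csv"), row.names = FALSE)
  fracs <- expanded_fraction_by_subset(clonotypes)
  exp_comp <- tryCatch(compare_expansion(fracs, meta, "post"),
                       error = function(e) NULL)
  if (!is.null(exp_comp))
    write.csv(exp_comp, out("expansion_compare.csv"), row.names = FALSE)
  manifest <- stage_log(manifest, "tcr", nrow(clonotypes), " clonotypes, ",
                        "mean chao1 ", signif(mean(div$chao1), 4))

  # -- cutpoint forest ------------------------------------------------------
  post_meta <- meta[meta$timepoint == "post", ]
  post_props <- props[intersect(rownames(props), post_meta$sample_id), ,
                      drop = FALSE]
  mm <- post_meta[match(rownames(post_props), post_meta$sample_id), ]
  forest <- run_stage("cutpoint-forest", suppressWarnings(
    cutpoint_forest(post_props, mm$pfs_days, mm$event,
                    bounds = config$cutpoint_bounds,
                    min_group_size = config$min_group_size)))
  write.csv(forest, out("forest.csv"), row.names = FALSE)
  manifest <- stage_log(manifest, "cutpoint-forest", nrow(forest),
                        " features with admissible cutpoints")

  # -- risk model -----------------------------------------------------------
  if (config$run_model) {
    keep <- mm$progressed_at_post %||% rep(0, nrow(mm))
    model_meta <- mm[keep == 0, ]
    mp <- post_props[model_meta$sample_id, , drop = FALSE]
    rownames(mp) <- model_meta$patient_id
    extras <- data.frame(patient_id = model_meta$patient_id,
                         age = model_meta$age, stringsAsFactors = FALSE)
    if (all(c("NK CD56bright", "NK CD56dim") %in% colnames(mp)))
      extras$cd56_ratio <- suppressMessages(cd56_ratio(mp))
    dm <- match(model_meta$sample_id, div$sample_id)
    if (!anyNA(dm)) extras$tcr_diversity <- div$chao1[dm]
    fm <- run_stage("model", suppressWarnings(build_features(mp, extras)))
    outcomes <- data.frame(patient_id = model_meta$patient_id,
                           time = model_meta$pfs_days,
                           event = model_meta$event)
    ens <- run_stage("model", loocv_ensemble(
      fm, outcomes, nlambda = config$nlambda,
      lambda_min_ratio = config$lambda_min_ratio,
      inner_folds = config$inner_folds, seed = config$seed))
    model <- select_model(ens, fm, outcomes)
    write_model_json(model, out("model.json"), seed = config$seed)
    write.csv(ens$summary, out("ensemble_summary.csv"), row.names = FALSE)
    oof <- ens$oof_scores
    write.csv(data.frame(patient_id = names(oof), oof_score = oof),
              out("scores.csv"), row.names = FALSE)
    strat <- tryCatch(
      stratify_and_test(oof[!is.na(oof)], outcomes$time[!is.na(oof)],
                        outcomes$event[!is.na(oof)], "median"),
      error = function(e) {
        warning("stratification skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(strat))
      write.csv(data.frame(patient_id = names(oof)[!is.na(oof)],
                           risk = strat$labels),
                out("strata.csv"), row.names = FALSE)
    manifest$model <- list(r2 = model$r2, lambda = model$lambda,
                           n_nonzero = sum(model$coef != 0),
                           strat_chisq = strat$chisq %||% NA,
                           strat_p = strat$p_value %||% NA,
                           n_high = strat$n_high %||% NA,
                           n_low = strat$n_low %||% NA)
    manifest <- stage_log(manifest, "model", "R2 ", signif(model$r2, 4),
                          ", stratification p ",
                          signif(manifest$model$strat_p, 3))
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- basename(files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
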