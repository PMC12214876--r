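require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(df)
}

#' Read an annotated cell table (TSV)
#'
#' Schema: `sample_id`, `barcode`, `n_genes`, `pct_mito`, `lineage`,
#' `subcluster`. Duplicated `(sample_id, barcode)` pairs and out-of-range
#' mitochondrial percentages are errors.
#'
#' @param path TSV file path.
#' @return data.frame of cell records.
#' @export
read_cells_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, c("sample_id", "barcode", "n_genes", "pct_mito",
                        "lineage", "subcluster"), path)
  dup <- duplicated(paste(df$sample_id, df$barcode, sep = "\r"))
  if (any(dup))
    stop("file '", path, "': duplicated (sample_id, barcode) pairs, e.g. ",
         df$barcode[which(dup)[1]])
  if (any(df$pct_mito < 0 | df$pct_mito > 100))
    stop("file '", path, "': pct_mito outside [0, 100]")
  if (any(df$n_genes < 0)) stop("file '", path, "': negative n_genes")
  df
}

#' Read an AIRR-style clonotype table (TSV)
#'
#' Schema: `sample_id`, `clone_id`, `cdr3_nt`, `v_call`, `j_call`, `subset`,
#' `cell_count` (positive integers).
#'
#' @param path TSV file path.
#' @return data.frame of clonotype records.
#' @export
read_clonotypes_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, c("sample_id", "clone_id", "subset", "cell_count"), path)
  if (any(df$cell_count < 1 | df$cell_count != round(df$cell_count)))
    stop("file '", path, "': cell_count must be positive integers")
  if (anyDuplicated(paste(df$sample_id, df$clone_id, sep = "\r")))
    stop("file '", path, "': duplicated (sample_id, clone_id) pairs")
  df
}

#' Read sample metadata (CSV)
#'
#' Schema: `sample_id`, `patient_id`, `timepoint` (pre/post), `group`,
#' `pfs_days` (> 0), `event` (0/1); further columns pass through.
#'
#' @param path CSV file path.
#' @return data.frame of sample metadata.
#' @export
read_meta_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, c("sample_id", "patient_id", "timepoint", "group",
                        "pfs_days", "event"), path)
  if (!all(df$timepoint %in% c("pre", "post")))
    stop("file '", path, "': timepoint must be 'pre' or 'post'")
  if (any(df$pfs_days <= 0)) stop("file '", path, "': pfs_days must be > 0")
  if (!all(df$event %in% c(0, 1))) stop("file '", path, "': event must be 0/1")
  df
}

#' Read a flow-panel lineage percentage table (CSV)
#'
#' Schema: `sample_id` plus one numeric column per lineage gate. The unit
#' must be declared; values inconsistent with the declared unit (e.g. a
#' table declared percent whose values never exceed 1.5) raise an error
#' rather than being silently rescaled.
#'
#' @param path CSV file path.
#' @param unit `"percent"` (0-100, default) or `"fraction"` (0-1).
#' @return data.frame with percentages 0-100 regardless of the input unit.
#' @export
read_flow_csv <- function(path, unit = c("percent", "fraction")) {
  unit <- match.arg(unit)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, "sample_id", path)
  vals <- unlist(df[setdiff(names(df), "sample_id")])
  if (unit == "percent" && max(vals, na.rm = TRUE) <= 1.5)
    stop("file '", path, "' declared percent (0-100) but values never exceed ",
         "1.5; declare unit = \"fraction\" if these are fractions")
  if (unit == "fraction" && max(vals, na.rm = TRUE) > 1.5)
    stop("file '", path, "' declared fraction (0-1) but contains values > 1.5")
  if (unit == "fraction")
    for (col in setdiff(names(df), "sample_id")) df[[col]] <- 100 * df[[col]]
  df
}

#' Read a per-sample proportion matrix (CSV)
#'
#' Schema: `sample_id` plus one fraction column per cell type; every row
#' must sum to 1 (tolerance 1e-6) or the offending sample is named in the
#' error.
#'
#' @param path CSV file path.
#' @return Numeric matrix with sample row names.
#' @export
read_proportions_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  require_columns(df, "sample_id", path)
  m <- as.matrix(df[setdiff(names(df), "sample_id")])
  rownames(m) <- df$sample_id
  sums <- rowSums(m)
  bad <- abs(sums - 1) > 1e-6
  if (any(bad))
    stop("file '", path, "': proportions of sample '",
         rownames(m)[which(bad)[1]], "' sum to ", signif(sums[which(bad)[1]], 6),
         ", not 1")
  if (any(m < 0 | m > 1)) stop("file '", path, "': values outside [0, 1]")
  m
}

#' Write a proportion matrix as CSV
#' @param props Proportion matrix with sample row names.
#' @param path Output CSV path.
#' @export
write_proportions_csv <- function(props, path) {
  df <- data.frame(sample_id = rownames(props), props, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
}

#' Write a Kaplan-Meier curve as CSV
#' @param km A [km_estimate()] result.
#' @param path Output CSV path.
#' @export
write_km_csv <- function(km, path) {
  write.csv(km$curve, path, row.names = FALSE)
}

#' Serialize a fitted risk model to JSON
#'
#' Stores the nonzero coefficients, penalty, standardization parameters,
#' feature space, training pseudo-R2 and its definition.
#'
#' @param model A `risk_model`.
#' @param path Output JSON path.
#' @param seed Optional provenance seed recorded alongside the model.
#' @export
write_model_json <- function(model, path, seed = NULL) {
  nz <- model$coef[model$coef != 0]
  obj <- list(
    coefficients = as.list(nz),
    lambda = model$lambda,
    center = as.list(model$center),
    scale = as.list(model$scale),
    features = model$features,
    mains = model$mains,
    r2 = model$r2 %||% NA,
    r2_definition = model$r2_definition %||% NA,
    n_train = model$n_train,
    seed = seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Load a risk model from JSON
#' @param path JSON path written by [write_model_json()].
#' @return A `risk_model` object.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coef <- setNames(rep(0, length(obj$features)), obj$features)
  coef[names(obj$coefficients)] <- unlist(obj$coefficients)
  structure(list(coef = coef, lambda = obj$lambda,
                 center = unlist(obj$center), scale = unlist(obj$scale),
                 features = obj$features, mains = obj$mains,
                 r2 = obj$r2, r2_definition = obj$r2_definition,
                 n_train = obj$n_train),
            class = "risk_model")
}

#' Read a run configuration from YAML
#'
#' Flat YAML file whose keys are [run_config()] arguments; `sim:` holds
#' [sim_config()] arguments.
#'
#' @param path YAML path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  y$sim <- do.call(sim_config, sim_args)
  do.call(run_config, y)
}
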