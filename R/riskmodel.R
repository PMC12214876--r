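#' CD56bright/CD56dim NK ratio
#'
#' Per-sample ratio of the CD56bright to the CD56dim NK proportion. Samples
#' with a zero denominator get a pseudocount of half the smallest nonzero
#' proportion of either column added to both numerator and denominator, with
#' a message naming how many samples were adjusted.
#'
#' @param props Proportion matrix containing both columns.
#' @param bright,dim Column labels.
#' @return Named numeric vector of ratios.
#' @export
cd56_ratio <- function(props, bright = "NK CD56bright", dim = "NK CD56dim") {
  stopifnot(all(c(bright, dim) %in% colnames(props)))
  num <- props[, bright]; den <- props[, dim]
  zero <- den == 0
  if (any(zero)) {
    eps <- min(c(num[num > 0], den[den > 0])) / 2
    message(sum(zero), " sample(s) with zero CD56dim proportion; pseudocount ",
            signif(eps, 3), " applied")
    num[zero] <- num[zero] + eps
    den[zero] <- den[zero] + eps
  }
  num / den
}

#' Build the interaction feature matrix for the progression model
#'
#' Combines per-patient main covariates (cell-type proportions plus optional
#' extras such as the CD56bright/CD56dim ratio, TCR diversity and age) with
#' all pairwise products of the main covariates. Products are computed on
#' the raw covariates, then every column is z-scored; the standardization
#' parameters are stored with the matrix. Interaction columns are named
#' `"A::B"` with labels in lexicographic order. Constant columns are dropped
#' with a warning. Patients missing any extra covariate are dropped with a
#' warning.
#'
#' @param props Proportion matrix, rows named by patient (post-transplant
#'   samples, already restricted to patients not progressed at sampling).
#' @param extras Optional data.frame with `patient_id` plus numeric columns.
#' @param interactions Include pairwise products (default TRUE).
#' @return Object of class `feature_matrix`: list with `x` (z-scored),
#'   `x_raw`, `center`, `scale`, `features`, `mains`, `patients`.
#' @export
build_features <- function(props, extras = NULL, interactions = TRUE) {
  mains <- as.matrix(props)
  patients <- rownames(mains)
  if (is.null(patients)) stop("props must have patient row names")
  if (!is.null(extras)) {
    stopifnot("patient_id" %in% names(extras))
    m <- match(patients, extras$patient_id)
    vals <- extras[m, setdiff(names(extras), "patient_id"), drop = FALSE]
    bad <- !stats::complete.cases(vals) | is.na(m)
    if (any(bad)) {
      warning("dropping ", sum(bad), " patient(s) with missing extras: ",
              paste(patients[bad], collapse = ", "))
      mains <- mains[!bad, , drop = FALSE]
      vals <- vals[!bad, , drop = FALSE]
      patients <- patients[!bad]
    }
    mains <- cbind(mains, as.matrix(vals))
  }
  main_names <- colnames(mains)
  raw <- mains
  if (interactions && ncol(mains) >= 2) {
    pairs <- combn(main_names, 2)
    inter <- mains[, pairs[1, ], drop = FALSE] * mains[, pairs[2, ], drop = FALSE]
    colnames(inter) <- interaction_name(pairs[1, ], pairs[2, ])
    raw <- cbind(raw, inter)
  }
  sds <- apply(raw, 2, sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant feature column(s): ",
            paste(colnames(raw)[sds == 0], collapse = ", "))
    raw <- raw[, sds > 0, drop = FALSE]
  }
  ctr <- colMeans(raw)
  scl <- apply(raw, 2, sd)
  x <- sweep(sweep(raw, 2, ctr, "-"), 2, scl, "/")
  structure(list(x = x, x_raw = raw, center = ctr, scale = scl,
                 features = colnames(raw),
                 mains = intersect(main_names, colnames(raw)),
                 patients = patients),
            class = "feature_matrix")
}

standardize_with <- function(raw, center, scale) {
  sweep(sweep(raw, 2, center, "-"), 2, scale, "/")
}

#' Leave-one-out ensemble of penalized Cox models
#'
#' For each patient, fits an L1 Cox path on the remaining patients (features
#' re-standardized on the training patients only, so held-out patients never
#' influence fitting or standardization), selects the penalty by inner
#' k-fold cross-validated partial-likelihood deviance with a seed derived
#' from the fold index, scores the held-out patient with that fold's model,
#' and counts the sign of every nonzero coefficient across the ensemble.
#' Folds whose training part has no events are skipped and recorded.
#'
#' @param fm A [build_features()] object.
#' @param outcomes data.frame with `patient_id`, `time`, `event` covering
#'   `fm$patients`.
#' @param nlambda,lambda_min_ratio Penalty-path parameters.
#' @param inner_folds Inner cross-validation folds for penalty selection.
#' @param seed Base seed; fold `i` uses `seed + i` for its inner fold
#'   assignment.
#' @return Object of class `loocv_ensemble`: list with `models` (per-fold
#'   coefficient vectors, penalty, standardization), `oof_scores` (named by
#'   patient; `NA` for skipped folds), `summary` (per feature: `n_positive`,
#'   `n_negative`, `n_models`), `skipped`.
#' @export
loocv_ensemble <- function(fm, outcomes, nlambda = 30, lambda_min_ratio = 0.05,
                           inner_folds = 5, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  m <- match(fm$patients, outcomes$patient_id)
  if (any(is.na(m))) stop("outcomes missing for: ",
                          paste(fm$patients[is.na(m)], collapse = ", "))
  time <- outcomes$time[m]; event <- outcomes$event[m]
  n <- length(fm$patients)
  if (n < 10) stop("at least 10 patients are required")
  models <- vector("list", n)
  oof <- stats::setNames(rep(NA_real_, n), fm$patients)
  skipped <- character(0)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (sum(event[tr]) < 1) { skipped <- c(skipped, fm$patients[i]); next }
    raw_tr <- fm$x_raw[tr, , drop = FALSE]
    ctr <- colMeans(raw_tr)
    scl <- apply(raw_tr, 2, sd)
    scl[scl == 0] <- 1   # constant-in-fold columns become all-zero features
    x_tr <- standardize_with(raw_tr, ctr, scl)
    lam <- lambda_path(x_tr, time[tr], event[tr], nlambda, lambda_min_ratio)
    cv <- cv_l1_cox(x_tr, time[tr], event[tr], lambda = lam,
                    nfolds = inner_folds, seed = seed + i)
    fit <- fit_l1_cox(x_tr, time[tr], event[tr], lambda = lam)
    beta <- coef_l1_cox(fit, cv$lambda_min)
    z_i <- (fm$x_raw[i, ] - ctr) / scl
    oof[i] <- sum(z_i * beta)
    models[[i]] <- list(patient_held_out = fm$patients[i], coef = beta,
                        lambda = cv$lambda_min, center = ctr, scale = scl,
                        features = fm$features, mains = fm$mains,
                        loglik = fit$loglik[which.min(abs(fit$lambda - cv$lambda_min))],
                        n_train = length(tr))
  }
  models <- models[!vapply(models, is.null, logical(1))]
  n_models <- length(models)
  coef_mat <- vapply(models, function(mm) mm$coef, numeric(length(fm$features)))
  summary <- data.frame(
    feature = fm$features,
    n_positive = rowSums(coef_mat > 0),
    n_negative = rowSums(coef_mat < 0),
    n_models = n_models,
    is_interaction = grepl("::", fm$features, fixed = TRUE),
    stringsAsFactors = FALSE
  )
  structure(list(models = models, oof_scores = oof, summary = summary,
                 skipped = skipped, time = time, event = event,
                 patients = fm$patients),
            class = "loocv_ensemble")
}

model_r2 <- function(model, fm, time, event) {
  lp <- score_patients(model, fm)
  n <- length(lp)
  l0 <- cox_loglik(rep(0, n), time, event)
  l1 <- cox_loglik(lp, time, event)
  1 - exp(2 * (l0 - l1) / n)
}

#' Select the ensemble model with the highest training pseudo-R2
#'
#' Scores the full training cohort with every leave-one-out model and
#' computes the Cox-Snell pseudo-R2 on the partial likelihood,
#' `1 - exp(2 (l0 - l_model) / n)`, where the model enters as a fixed linear
#' predictor. The highest-R2 model wins; ties are broken by fewer nonzero
#' coefficients. The zero model scores exactly 0.
#'
#' @param ensemble A [loocv_ensemble()] object.
#' @param fm The training [build_features()] matrix.
#' @param outcomes data.frame with `patient_id`, `time`, `event`.
#' @return The selected model (class `risk_model`), with `r2`,
#'   `r2_definition` and the per-model R2 vector attached as `all_r2`.
#' @export
select_model <- function(ensemble, fm, outcomes) {
  stopifnot(inherits(ensemble, "loocv_ensemble"))
  m <- match(fm$patients, outcomes$patient_id)
  time <- outcomes$time[m]; event <- outcomes$event[m]
  r2 <- vapply(ensemble$models, model_r2, numeric(1), fm = fm,
               time = time, event = event)
  nnz <- vapply(ensemble$models, function(mm) sum(mm$coef != 0), numeric(1))
  best <- order(-r2, nnz)[1]
  model <- ensemble$models[[best]]
  model$r2 <- r2[best]
  model$r2_definition <- "Cox-Snell on the Efron partial likelihood"
  model$all_r2 <- r2
  class(model) <- "risk_model"
  model
}

#' Hazard score of patients under a fitted risk model
#'
#' Linear predictor `z . beta` on features standardized with the model's
#' stored training parameters. Higher scores predict earlier progression.
#' The input may be a [build_features()] object or a raw feature matrix with
#' exactly the model's feature columns.
#'
#' @param model A `risk_model` (or a single ensemble member).
#' @param features A `feature_matrix` or raw numeric matrix in model space.
#' @return Named numeric vector of per-patient hazard scores.
#' @export
score_patients <- function(model, features) {
  raw <- if (inherits(features, "feature_matrix")) features$x_raw
         else as.matrix(features)
  if (!setequal(colnames(raw), model$features))
    stop("feature names do not match the model's feature space")
  raw <- raw[, model$features, drop = FALSE]
  z <- standardize_with(raw, model$center, model$scale)
  drop(z %*% model$coef)
}

#' Map an external cohort into a model's feature space
#'
#' Harmonizes external cell-type labels to the model's main covariates using
#' a many-to-one source-to-target map (mapped proportions are summed),
#' recomputes the model's interaction features from the harmonized mains,
#' and standardizes with the model's stored training parameters. Model
#' features whose sources are absent from the external cohort are imputed at
#' the training mean — standardized value exactly 0, contributing nothing to
#' any score — and listed in the `imputed` attribute. Unmapped source
#' columns are dropped with a warning; a map target absent from the model's
#' main covariates is an error.
#'
#' @param external_props External proportion matrix (rows = patients,
#'   columns = source labels).
#' @param map data.frame with columns `source_label`, `target_label`.
#' @param model A `risk_model`.
#' @param extras Optional data.frame (`patient_id` + columns named like
#'   model main covariates, e.g. `age`).
#' @return Raw feature matrix in model space (attribute `imputed` lists the
#'   mean-imputed features); pass to [score_patients()].
#' @export
harmonize <- function(external_props, map, model, extras = NULL) {
  stopifnot(all(c("source_label", "target_label") %in% names(map)))
  bad_target <- setdiff(unique(map$target_label), model$mains)
  if (length(bad_target))
    stop("map target(s) absent from the model's main covariates: ",
         paste(bad_target, collapse = ", "))
  ext <- as.matrix(external_props)
  unmapped <- setdiff(colnames(ext), map$source_label)
  if (length(unmapped))
    warning("dropping unmapped source column(s): ",
            paste(unmapped, collapse = ", "))
  patients <- rownames(ext)
  mains <- matrix(NA_real_, nrow(ext), length(model$mains),
                  dimnames = list(patients, model$mains))
  for (tgt in unique(map$target_label)) {
    src <- intersect(map$source_label[map$target_label == tgt], colnames(ext))
    if (length(src))
      mains[, tgt] <- rowSums(ext[, src, drop = FALSE])
  }
  if (!is.null(extras)) {
    stopifnot("patient_id" %in% names(extras))
    m <- match(patients, extras$patient_id)
    for (col in intersect(setdiff(names(extras), "patient_id"), model$mains))
      mains[, col] <- extras[[col]][m]
  }
  present <- colnames(mains)[colSums(is.na(mains)) == 0]
  raw <- matrix(NA_real_, nrow(ext), length(model$features),
                dimnames = list(patients, model$features))
  for (f in model$features) {
    if (f %in% colnames(mains)) {
      raw[, f] <- mains[, f]
    } else if (grepl("::", f, fixed = TRUE)) {
      ab <- strsplit(f, "::", fixed = TRUE)[[1]]
      if (all(ab %in% colnames(mains)))
        raw[, f] <- mains[, ab[1]] * mains[, ab[2]]
    }
  }
  imputed <- model$features[colSums(is.na(raw)) > 0]
  for (f in imputed) raw[, f] <- model$center[[f]]
  if (length(imputed))
    message(length(imputed),
            " model feature(s) without source data imputed at the training mean")
  attr(raw, "imputed") <- imputed
  raw
}

#' Stratify patients by hazard score and test the separation
#'
#' Splits patients into high and low risk at the median score (training
#' evaluation of out-of-fold scores) or at an upper percentile (external
#' evaluation; the study-style stringent cutoff is the 80th percentile), and
#' runs a log-rank test between the strata.
#'
#' @param scores Per-patient hazard scores.
#' @param time,event Survival outcome vectors, aligned with `scores`.
#' @param cutoff `"median"` or a percentile in (0, 1), e.g. `0.8`.
#' @return List with `labels` ("high"/"low"), `threshold`, `n_high`,
#'   `n_low`, `chisq`, `p_value`.
#' @export
stratify_and_test <- function(scores, time, event, cutoff = "median") {
  if (length(unique(scores)) < 2) stop("all scores identical; no split possible")
  thr <- if (identical(cutoff, "median")) median(scores)
         else if (is.numeric(cutoff) && cutoff > 0 && cutoff < 1)
           quantile(scores, cutoff, names = FALSE)
         else stop("cutoff must be \"median\" or a percentile in (0, 1)")
  labels <- ifelse(scores > thr, "high", "low")
  if (length(unique(labels)) < 2) stop("degenerate split at the chosen cutoff")
  lr <- logrank_test(time, event, labels)
  list(labels = labels, threshold = thr,
       n_high = sum(labels == "high"), n_low = sum(labels == "low"),
       chisq = lr$chisq, p_value = lr$p_value)
}

#' Rank-sum comparison of hazard scores between two patient groups
#'
#' Two-sided Wilcoxon rank-sum test: exact when the combined sample size is
#' at most 20 and the scores have no ties, otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param scores Numeric hazard scores.
#' @param group Two-level grouping vector aligned with `scores`.
#' @return List with `p_value`, `statistic` (rank-sum W of the first group),
#'   `exact`.
#' @export
hazard_group_test <- function(scores, group) {
  group <- as.character(group)
  lv <- sort(unique(group))
  if (length(lv) != 2) stop("exactly two groups are required")
  a <- scores[group == lv[1]]; b <- scores[group == lv[2]]
  if (!length(a) || !length(b)) stop("empty group")
  exact <- (length(a) + length(b)) <= 20 && !anyDuplicated(c(a, b))
  wt <- wilcox.test(a, b, exact = exact, correct = TRUE)
  list(p_value = wt$p.value, statistic = unname(wt$statistic), exact = exact)
}
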