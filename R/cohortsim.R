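#' Default bone-marrow cell-type catalog
#'
#' Thirty-five immune and stromal subclusters of the CD138-depleted bone
#' marrow, each assigned to a coarse lineage and given a baseline composition
#' weight (relative Dirichlet mean). The first eight rows span the subclusters
#' most relevant to progression modeling (exhausted/memory CD8 T cells,
#' stromal cells, dendritic cells, monocytes, NK subsets) so that reduced
#' simulations with few cell types still exercise the model's feature set.
#'
#' @return A data.frame with columns `subcluster`, `lineage`, `weight`.
#' @export
default_celltypes <- function() {
  df <- data.frame(
    subcluster = c(
      "CD8 T exhausted", "Stromal", "pDC", "CD14 monocyte",
      "NK CD56bright", "NK CD56dim", "CD8 T memory", "mDC",
      "B naive", "B memory", "B intermediate", "Precursor B", "Pre-pro B",
      "Plasmablast", "CD4 T naive", "CD4 T memory", "CD4 T effector",
      "CD4 T regulatory", "CD4 T CTL", "CD8 T naive", "CD8 T effector",
      "CD8 T exhausted proliferative", "CD8 T other", "NK other",
      "CD16 monocyte", "Myeloid progenitor", "Macrophage", "HSC",
      "B progenitor", "Erythroid progenitor", "GMP", "ILC", "MAIT",
      "gdT", "Platelet"
    ),
    lineage = c(
      "CD8 T", "stromal", "pDC", "monocyte/myeloid",
      "NK", "NK", "CD8 T", "mDC",
      "B", "B", "B", "B", "B",
      "B", "CD4 T", "CD4 T", "CD4 T",
      "CD4 T", "CD4 T", "CD8 T", "CD8 T",
      "CD8 T", "CD8 T", "NK",
      "monocyte/myeloid", "monocyte/myeloid", "monocyte/myeloid", "progenitor",
      "progenitor", "progenitor", "progenitor", "other", "other",
      "other", "other"
    ),
    weight = c(
      6, 1.5, 1.2, 6,
      1.2, 0.8, 2.5, 1.0,
      6, 4, 3, 5, 2,
      1, 8, 6, 4,
      2, 1.5, 5, 8,
      1, 2, 0.8,
      2.5, 3, 1, 1.5,
      1, 3, 1.5, 0.8, 1.2,
      1.5, 1
    ),
    stringsAsFactors = FALSE
  )
  df
}

# Default progressor-vs-nonprogressor log-fold shifts on the Dirichlet mean,
# matching the direction and approximate magnitude of the composition
# differences the downstream comparisons are designed to detect: more
# exhausted/memory CD8 T cells in progressors, fewer B/myeloid progenitors,
# monocytes and pDCs.
default_group_shifts <- function(subclusters) {
  shifts <- stats::setNames(rep(0, length(subclusters)), subclusters)
  known <- c(
    "CD8 T exhausted" = 0.58, "CD8 T memory" = 0.54,
    "pDC" = -0.32, "CD14 monocyte" = -0.35,
    "Myeloid progenitor" = -0.39, "B progenitor" = -0.60
  )
  hit <- intersect(names(known), subclusters)
  shifts[hit] <- known[hit]
  shifts
}

#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults emulate
#' the study design the downstream analysis targets: 40 patients sampled
#' before and after transplant, 35 annotated subclusters whose per-sample
#' proportions follow group-shifted Dirichlet distributions, progression
#' hazards that are log-linear in composition features, heavy-tailed TCR
#' clone sizes concentrated in CD8 subsets, and a noisy aggregated flow-panel
#' view of the same samples.
#'
#' Hazard coefficients (`beta_main`, `beta_interactions`,
#' `group_hazard_offset`) are per-standard-deviation log-hazard ratios: each
#' named feature (a proportion, or a pairwise product of proportions) is
#' z-scored across the cohort before the linear predictor is formed, so a
#' coefficient of 0.7 means a 2x hazard per SD of that feature.
#'
#' @param n_patients Number of patients (each contributes a pre- and a
#'   post-transplant sample).
#' @param n_celltypes Number of subclusters; the first `n_celltypes` rows of
#'   `celltypes` are used.
#' @param celltypes Catalog data.frame (`subcluster`, `lineage`, `weight`);
#'   defaults to [default_celltypes()].
#' @param cells_per_sample Cells drawn per sample (multinomial given the
#'   sample's true proportions).
#' @param base_composition Positive weights (length `n_celltypes`) for the
#'   nonprogressor Dirichlet mean; default from the catalog.
#' @param group_logfold_shifts Named or plain numeric vector of log-fold
#'   shifts applied multiplicatively to the progressor-group Dirichlet mean
#'   (then renormalized).
#' @param dirichlet_precision Dirichlet concentration (sum of alphas).
#' @param beta_main Named numeric vector: per-SD log-hazard per cell-type
#'   proportion.
#' @param beta_interactions Named numeric vector over `"A::B"` pairs: per-SD
#'   log-hazard of the proportion product. Names are canonicalized.
#' @param group_hazard_offset Extra log-hazard for latent progressor-group
#'   patients, tying the ground-truth group label to observed progression.
#' @param baseline_shape,baseline_scale Weibull baseline parameters (days).
#' @param censor_time Administrative censoring time (days).
#' @param clone_size_exponent Power-law exponent (> 1) of TCR clone sizes.
#' @param expansion_shift Reduction of the exponent for progressor post-ASCT
#'   samples (heavier tail, more expansion).
#' @param cd8_expanded_frac Fraction of expanded clones assigned to CD8
#'   subsets (the rest go to CD4).
#' @param flow_sigma SD of additive logit-scale noise on the flow-panel view.
#' @param prob_progressor Prior probability of the latent progressor group.
#' @param post_sample_day Day (post-transplant) the "post" sample represents;
#'   used to flag patients already progressed at sampling.
#' @param seed Integer seed; identical configurations reproduce identical
#'   cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 40,
                       n_celltypes = 35,
                       celltypes = default_celltypes(),
                       cells_per_sample = 6000,
                       base_composition = NULL,
                       group_logfold_shifts = NULL,
                       dirichlet_precision = 60,
                       beta_main = c("CD8 T exhausted" = 0.4),
                       beta_interactions = c("CD8 T exhausted::Stromal" = 0.8,
                                             "CD8 T exhausted::mDC" = 0.6,
                                             "CD14 monocyte::pDC" = -0.5),
                       group_hazard_offset = 1.0,
                       baseline_shape = 1,
                       baseline_scale = 2500,
                       censor_time = 1800,
                       clone_size_exponent = 3,
                       expansion_shift = 0.3,
                       cd8_expanded_frac = 0.96,
                       flow_sigma = 0.3,
                       prob_progressor = 0.5,
                       post_sample_day = 100,
                       seed = 1L) {
  stopifnot(is.data.frame(celltypes),
            all(c("subcluster", "lineage", "weight") %in% names(celltypes)))
  if (n_patients < 1 || n_celltypes < 1 || cells_per_sample < 1)
    stop("n_patients, n_celltypes and cells_per_sample must all be >= 1")
  if (n_celltypes > nrow(celltypes))
    stop("n_celltypes exceeds the catalog size (", nrow(celltypes), ")")
  ct <- celltypes[seq_len(n_celltypes), , drop = FALSE]
  types <- ct$subcluster

  if (is.null(base_composition)) base_composition <- ct$weight
  if (length(base_composition) != n_celltypes)
    stop("base_composition must have length n_celltypes")
  if (any(base_composition <= 0)) stop("base_composition must be strictly positive")
  if (dirichlet_precision <= 0) stop("dirichlet_precision must be > 0")
  if (censor_time <= 0) stop("censor_time must be > 0")
  if (baseline_shape <= 0 || baseline_scale <= 0)
    stop("baseline_shape and baseline_scale must be > 0")
  if (clone_size_exponent <= 1) stop("clone_size_exponent must be > 1")

  if (is.null(group_logfold_shifts)) {
    group_logfold_shifts <- default_group_shifts(types)
  } else if (is.null(names(group_logfold_shifts))) {
    if (length(group_logfold_shifts) == 1)
      group_logfold_shifts <- rep(group_logfold_shifts, n_celltypes)
    if (length(group_logfold_shifts) != n_celltypes)
      stop("group_logfold_shifts must be named or of length n_celltypes")
    names(group_logfold_shifts) <- types
  } else {
    full <- stats::setNames(rep(0, n_celltypes), types)
    unknown <- setdiff(names(group_logfold_shifts), types)
    if (length(unknown))
      stop("group_logfold_shifts names not in the catalog: ",
           paste(unknown, collapse = ", "))
    full[names(group_logfold_shifts)] <- group_logfold_shifts
    group_logfold_shifts <- full
  }

  beta_main_full <- stats::setNames(rep(0, n_celltypes), types)
  if (length(beta_main)) {
    keep <- intersect(names(beta_main), types)
    beta_main_full[keep] <- beta_main[keep]
  }
  bi <- numeric(0)
  if (length(beta_interactions)) {
    parts <- strsplit(names(beta_interactions), "::", fixed = TRUE)
    ok <- vapply(parts, function(p) length(p) == 2 && all(p %in% types), logical(1))
    bi <- beta_interactions[ok]
    if (length(bi))
      names(bi) <- vapply(parts[ok], function(p) interaction_name(p[1], p[2]),
                          character(1))
  }

  structure(list(
    n_patients = as.integer(n_patients), n_celltypes = as.integer(n_celltypes),
    celltypes = ct, cells_per_sample = as.integer(cells_per_sample),
    base_composition = base_composition,
    group_logfold_shifts = group_logfold_shifts,
    dirichlet_precision = dirichlet_precision,
    beta_main = beta_main_full, beta_interactions = bi,
    group_hazard_offset = group_hazard_offset,
    baseline_shape = baseline_shape, baseline_scale = baseline_scale,
    censor_time = censor_time,
    clone_size_exponent = clone_size_exponent,
    expansion_shift = expansion_shift,
    cd8_expanded_frac = cd8_expanded_frac,
    flow_sigma = flow_sigma,
    prob_progressor = prob_progressor,
    post_sample_day = post_sample_day,
    seed = as.integer(seed)
  ), class = "sim_config")
}

rdirichlet_one <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1  # pathological underflow guard
  g / sum(g)
}

# Discrete power-law clone sizes: floor of a Pareto(alpha) variate on [1, inf),
# so the histogram tail decays like k^-alpha.
rpowerlaw <- function(n, alpha) {
  pmax(1L, as.integer(floor(runif(n)^(-1 / (alpha - 1)))))
}

#' Simulate survival outcomes under a Weibull proportional-hazards model
#'
#' Inverts the Weibull baseline: `T = scale * (-log(U) / exp(lp))^(1/shape)`,
#' administratively censored at `censor`.
#'
#' @param linear_predictor Per-patient log-hazard (finite numeric vector).
#' @param shape,scale Weibull baseline parameters (both > 0).
#' @param censor Administrative censoring time.
#' @param seed Optional integer; when given, sampling is locally seeded.
#' @return data.frame with columns `time` (min of event time and `censor`)
#'   and `event` (1 if the event time is at or before `censor`).
#' @export
simulate_survival <- function(linear_predictor, shape, scale, censor, seed = NULL) {
  if (any(!is.finite(linear_predictor))) stop("linear_predictor must be finite")
  if (shape <= 0 || scale <= 0) stop("shape and scale must be > 0")
  draw <- function() {
    u <- runif(length(linear_predictor))
    t_event <- scale * (-log(u) / exp(linear_predictor))^(1 / shape)
    data.frame(time = pmin(t_event, censor),
               event = as.integer(t_event <= censor))
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Simulate per-sample cell-type proportion matrices
#'
#' Draws Dirichlet proportion vectors with a multiplicative (log-fold)
#' group shift on the mean — the compositional core of [simulate_cohort()],
#' exposed separately so that proportion-level statistics can be studied
#' without generating cell tables.
#'
#' @param n_samples Number of samples (rows).
#' @param mean_composition Positive base weights (normalized internally).
#' @param precision Dirichlet concentration.
#' @param logfold_shift Per-type log-fold shift applied to shifted samples.
#' @param shifted Logical vector (length `n_samples`): which rows get the
#'   shifted mean.
#' @return Matrix of proportions (rows sum to 1).
#' @export
simulate_proportions <- function(n_samples, mean_composition, precision,
                                 logfold_shift = 0, shifted = rep(FALSE, n_samples)) {
  if (any(mean_composition <= 0)) stop("mean_composition must be strictly positive")
  if (precision <= 0) stop("precision must be > 0")
  k <- length(mean_composition)
  base <- mean_composition / sum(mean_composition)
  shifted_mean <- base * exp(rep_len(logfold_shift, k))
  shifted_mean <- shifted_mean / sum(shifted_mean)
  out <- matrix(0, n_samples, k)
  for (i in seq_len(n_samples)) {
    m <- if (shifted[i]) shifted_mean else base
    out[i, ] <- rdirichlet_one(precision * m)
  }
  colnames(out) <- names(mean_composition)
  out
}

random_cdr3 <- function(n, len = 39L) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Fill the T-cell compartments of one sample with clones. Expanded clones
# (X > 1) are assigned to CD8 subsets with probability cd8_frac, CD4
# otherwise (overflowing to the other pool only when the preferred pool is
# full), then to a subcluster proportional to remaining capacity; remaining
# capacity is topped up with singletons.
simulate_sample_clones <- function(sample_id, subset_capacity, subset_lineage,
                                   alpha, cd8_frac) {
  total <- sum(subset_capacity)
  if (total == 0) return(NULL)
  sizes <- rpowerlaw(total, alpha)  # at most `total` clones needed
  sizes <- sizes[cumsum(sizes) <= total | seq_along(sizes) == 1]
  expanded <- sizes[sizes > 1]
  cap <- subset_capacity
  rows_subset <- character(0)
  rows_count <- integer(0)
  cd8_sets <- names(cap)[subset_lineage == "CD8 T"]
  cd4_sets <- names(cap)[subset_lineage == "CD4 T"]
  if (length(expanded)) {
    use_cd8 <- runif(length(expanded)) < cd8_frac
    rows_subset <- character(length(expanded))
    rows_count <- integer(length(expanded))
    for (i in seq_along(expanded)) {
      pools <- if (use_cd8[i]) list(cd8_sets, cd4_sets)
               else list(cd4_sets, cd8_sets)
      s <- NA_character_
      for (pool in pools) {
        avail <- cap[pool]
        avail <- avail[avail >= 2]
        if (length(avail)) {
          s <- if (length(avail) == 1) names(avail) else
            sample(names(avail), 1, prob = avail)
          break
        }
      }
      if (is.na(s)) next  # both pools full: the cells become singletons
      x <- min(expanded[i], cap[[s]])
      cap[[s]] <- cap[[s]] - x
      rows_subset[i] <- s
      rows_count[i] <- x
    }
    keep <- rows_count > 0L
    rows_subset <- rows_subset[keep]
    rows_count <- rows_count[keep]
  }
  # singletons fill every remaining T cell
  left <- cap[cap > 0]
  if (length(left)) {
    rows_subset <- c(rows_subset, rep(names(left), times = left))
    rows_count <- c(rows_count, rep(1L, sum(left)))
  }
  n <- length(rows_count)
  if (n == 0) return(NULL)
  v <- paste0("TRBV", sample(1:30, n, replace = TRUE))
  j <- paste0("TRBJ", sample(1:7, n, replace = TRUE))
  cdr3 <- random_cdr3(n)
  data.frame(
    sample_id = sample_id,
    clone_id = paste(v, j, cdr3, sep = "|"),
    cdr3_nt = cdr3, v_call = v, j_call = j,
    subset = rows_subset, cell_count = as.integer(rows_count),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full pre/post-transplant cohort
#'
#' Generates, from a single seed, every table the downstream pipeline
#' consumes: an annotated cell table with QC covariates, an AIRR-style
#' clonotype table, per-sample clinical metadata with progression outcomes,
#' an aggregated noisy flow-panel view, and a ground-truth record for
#' recovery tests.
#'
#' Generative model: each patient carries a latent progression-risk group;
#' per-sample subcluster proportions are Dirichlet with a group-shifted mean;
#' cell counts are multinomial given proportions; progression times follow a
#' Weibull proportional-hazards model whose linear predictor combines
#' z-scored post-transplant composition features (main effects and the
#' configured pairwise products) with the latent group offset; clone sizes
#' are discrete power-law, truncated by subset capacity, with expanded clones
#' concentrated in CD8 subsets; the flow table aggregates lineages with
#' additive logit-scale noise.
#'
#' @param config A [sim_config()] object.
#' @return List of class `sim_cohort` with elements `cells`, `clonotypes`,
#'   `meta`, `flow`, `truth` and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$cells_per_sample < config$n_celltypes)
    warning("cells_per_sample is smaller than the number of cell types; ",
            "rare types will often be absent")
  with_local_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  ct <- config$celltypes
  types <- ct$subcluster
  k <- config$n_celltypes
  npat <- config$n_patients
  pid <- sprintf("P%03d", seq_len(npat))
  group <- ifelse(runif(npat) < config$prob_progressor, "progressor", "nonprogressor")
  age <- round(runif(npat, 45, 72))

  timepoints <- c("pre", "post")
  sample_id <- as.vector(vapply(pid, function(p) paste(p, timepoints, sep = "_"),
                                character(2)))
  samp_pat <- rep(pid, each = 2)
  samp_tp <- rep(timepoints, npat)
  samp_group <- rep(group, each = 2)

  props <- simulate_proportions(
    n_samples = length(sample_id),
    mean_composition = stats::setNames(config$base_composition, types),
    precision = config$dirichlet_precision,
    logfold_shift = config$group_logfold_shifts,
    shifted = samp_group == "progressor"
  )
  rownames(props) <- sample_id

  # hazard features from post-transplant true composition, z-scored cohort-wide
  post_rows <- samp_tp == "post"
  post_props <- props[post_rows, , drop = FALSE]
  rownames(post_props) <- samp_pat[post_rows]
  lp <- rep(0, npat)
  zcol <- function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  for (tn in names(config$beta_main)) {
    b <- config$beta_main[[tn]]
    if (b != 0) lp <- lp + b * zcol(post_props[, tn])
  }
  for (pn in names(config$beta_interactions)) {
    b <- config$beta_interactions[[pn]]
    ab <- strsplit(pn, "::", fixed = TRUE)[[1]]
    lp <- lp + b * zcol(post_props[, ab[1]] * post_props[, ab[2]])
  }
  lp <- lp + config$group_hazard_offset * (group == "progressor")

  surv <- simulate_survival(lp, config$baseline_shape, config$baseline_scale,
                            config$censor_time)
  pfs_days <- pmax(1, round(surv$time))
  event <- surv$event

  # response / MRD labels tied to the true hazard (better outcome, lower lp)
  zresp <- lp + rnorm(npat)
  qs <- quantile(zresp, c(0.4, 0.85))
  response <- ifelse(zresp <= qs[1], "CR", ifelse(zresp <= qs[2], "VGPR", "PR"))
  mrd_sustained <- as.integer(zresp < quantile(zresp, 0.45))

  meta <- data.frame(
    sample_id = sample_id, patient_id = samp_pat, timepoint = samp_tp,
    group = samp_group,
    pfs_days = rep(pfs_days, each = 2), event = rep(event, each = 2),
    age = rep(age, each = 2), response = rep(response, each = 2),
    mrd_sustained = rep(mrd_sustained, each = 2),
    progressed_at_post = rep(as.integer(event == 1 &
                                          pfs_days <= config$post_sample_day),
                             each = 2),
    stringsAsFactors = FALSE
  )

  # cell table: multinomial counts, then per-cell QC covariates
  lin_map <- stats::setNames(ct$lineage, ct$subcluster)
  cells_list <- vector("list", length(sample_id))
  counts_mat <- matrix(0L, length(sample_id), k,
                       dimnames = list(sample_id, types))
  for (i in seq_along(sample_id)) {
    cnt <- as.integer(stats::rmultinom(1, config$cells_per_sample, props[i, ]))
    counts_mat[i, ] <- cnt
    n <- sum(cnt)
    sub <- rep(types, times = cnt)
    cells_list[[i]] <- data.frame(
      sample_id = sample_id[i],
      barcode = sprintf("%s-%05d", sample_id[i], seq_len(n)),
      n_genes = as.integer(rnbinom(n, size = 3, mu = 2200)),
      pct_mito = round(100 * rbeta(n, 2, 28), 3),
      lineage = unname(lin_map[sub]),
      subcluster = sub,
      stringsAsFactors = FALSE
    )
  }
  cells <- do.call(rbind, cells_list)
  rownames(cells) <- NULL

  # clonotypes: fill the T compartments with power-law clones
  t_sets <- types[ct$lineage %in% c("CD4 T", "CD8 T")]
  clono_list <- vector("list", length(sample_id))
  for (i in seq_along(sample_id)) {
    capacity <- stats::setNames(counts_mat[i, t_sets], t_sets)
    alpha <- config$clone_size_exponent -
      config$expansion_shift * (samp_group[i] == "progressor" && samp_tp[i] == "post")
    clono_list[[i]] <- simulate_sample_clones(
      sample_id[i], capacity, lin_map[t_sets], alpha, config$cd8_expanded_frac)
  }
  clonotypes <- do.call(rbind, clono_list)
  rownames(clonotypes) <- NULL

  # flow view: aggregated lineage proportions + logit noise, as percentages
  groups <- flow_lineage_groups()
  lineage_props <- t(vapply(seq_along(sample_id), function(i) {
    tapply(props[i, ], lin_map[types], sum)
  }, numeric(length(unique(ct$lineage)))))
  rownames(lineage_props) <- sample_id
  flow <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  for (g in names(groups)) {
    cols <- intersect(groups[[g]], colnames(lineage_props))
    if (!length(cols)) next
    p <- rowSums(lineage_props[, cols, drop = FALSE])
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    noisy <- inv_logit(logit(p) + rnorm(length(p), 0, config$flow_sigma))
    flow[[g]] <- round(100 * noisy, 4)
  }

  truth <- list(
    proportions = props,
    linear_predictor = stats::setNames(lp, pid),
    interaction_pairs = names(config$beta_interactions),
    group = stats::setNames(group, pid),
    uncensored_time = stats::setNames(surv$time, pid)
  )

  structure(list(cells = cells, clonotypes = clonotypes, meta = meta,
                 flow = flow, truth = truth, config = config),
            class = "sim_cohort")
}

#' Flow-panel lineage groupings
#'
#' How the aggregated flow-cytometry view groups the single-cell lineages:
#' mature B cells, combined T/NK cells, monocytic/myeloid cells (including
#' myeloid dendritic cells), progenitors, and a remainder gate. Granulocytes
#' are never generated (Ficoll-separated samples), so no granulocyte gate
#' exists to exclude.
#'
#' @return Named list mapping flow gate names to single-cell lineage labels.
#' @export
flow_lineage_groups <- function() {
  list(
    "B" = "B",
    "T/NK" = c("CD4 T", "CD8 T", "NK"),
    "monocyte" = c("monocyte/myeloid", "mDC"),
    "progenitor" = "progenitor",
    "other" = c("pDC", "stromal", "other")
  )
}
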