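# Shared fixtures and memoized heavy simulations.

# Small cohort config for fast structural tests.
small_config <- function(seed = 1, ...) {
  sim_config(n_patients = 12, cells_per_sample = 400, seed = seed, ...)
}

# Planted-interaction study conditions: 8 cell types, one pairwise
# interaction at 1.2 per-SD log-hazard, no other effects, n = 200 patients.
planted_pair <- "CD8 T exhausted::Stromal"

planted_config <- function(seed) {
  sim_config(n_patients = 200, n_celltypes = 8, cells_per_sample = 600,
             group_logfold_shifts = 0, beta_main = c(),
             beta_interactions = stats::setNames(1.2, planted_pair),
             group_hazard_offset = 0, seed = seed)
}

# One planted-interaction replicate: simulate, build features from computed
# proportions, run the leave-one-out ensemble. Memoized across test files
# because several properties are checked on the same replicates.
.replicate_cache <- new.env(parent = emptyenv())

planted_replicate <- function(r) {
  key <- paste0("rep", r)
  if (!is.null(.replicate_cache[[key]])) return(.replicate_cache[[key]])
  co <- simulate_cohort(planted_config(seed = 1000 + r))
  cells <- suppressMessages(qc_filter(co$cells))
  props <- compute_proportions(cells, "subcluster")
  post <- co$meta[co$meta$timepoint == "post", ]
  mp <- props[post$sample_id, , drop = FALSE]
  rownames(mp) <- post$patient_id
  fm <- build_features(mp)
  outc <- data.frame(patient_id = post$patient_id, time = post$pfs_days,
                     event = post$event)
  ens <- loocv_ensemble(fm, outc, seed = 1000 + r)
  res <- list(fm = fm, outcomes = outc, ensemble = ens)
  .replicate_cache[[key]] <- res
  res
}

# Well-conditioned toy proportion matrix for feature-construction tests.
toy_features <- function(n = 30, m = 4, seed = 1) {
  set.seed(seed)
  props <- matrix(abs(rnorm(n * m, 0.25, 0.08)), n, m)
  props <- props / rowSums(props)
  dimnames(props) <- list(sprintf("P%02d", 1:n), paste0("ct", 1:m))
  props
}

# Brute-force Efron partial-likelihood maximizer by nested grid refinement
# (independent of the Newton and coordinate-descent solvers).
grid_cox <- function(x, time, event, lo = -6, hi = 6, rounds = 9, pts = 25) {
  x <- as.matrix(x)
  p <- ncol(x)
  ll <- function(b) cox_loglik(drop(x %*% b), time, event)
  lo <- rep(lo, p); hi <- rep(hi, p)
  best <- rep(0, p)
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p), function(j) seq(lo[j], hi[j], length.out = pts))
    cand <- as.matrix(expand.grid(grids))
    vals <- apply(cand, 1, ll)
    best <- as.numeric(cand[which.max(vals), ])
    span <- (hi - lo) / (pts - 1)
    lo <- best - 2 * span
    hi <- best + 2 * span
  }
  best
}

# Exhaustive two-sided Fisher probability by direct binomial-coefficient
# arithmetic (independent of dhyper).
fisher_enumerate <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  pr <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  p_obs <- pr[xs == tab[1, 1]]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Exhaustive rank-sum p-value over all assignments of ranks to group 1.
ranksum_enumerate <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_w <- apply(combn(length(pooled), n1), 2,
                 function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- mean(all_w)
  mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-9)
}
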