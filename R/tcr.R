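#' Aggregate cell-level clonotype calls into a clonotype table
#'
#' Counts, within each sample, the number of cells sharing a clone key
#' (`clone_id`, conventionally the CDR3 nucleotide sequence composite with V
#' and J calls) and assigns each clone the majority subset of its member
#' cells, breaking ties lexicographically with a warning.
#'
#' @param records data.frame with columns `sample_id`, `clone_id`, `subset`
#'   (one row per cell).
#' @return data.frame with columns `sample_id`, `clone_id`, `subset`,
#'   `cell_count`; `(sample_id, clone_id)` unique.
#' @export
aggregate_clonotypes <- function(records) {
  stopifnot(all(c("sample_id", "clone_id", "subset") %in% names(records)))
  key <- paste(records$sample_id, records$clone_id, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  ties <- 0L
  rows <- lapply(groups, function(ix) {
    tab <- sort(table(records$subset[ix]), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      ties <<- ties + 1L
      winners <- names(tab)[tab == tab[1]]
      subset <- min(winners)
    } else {
      subset <- names(tab)[1]
    }
    data.frame(sample_id = records$sample_id[ix[1]],
               clone_id = records$clone_id[ix[1]],
               subset = subset, cell_count = length(ix),
               stringsAsFactors = FALSE)
  })
  if (ties > 0)
    warning(ties, " clone(s) had tied subset votes; ties broken lexicographically")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clonal-expansion category of a clonotype occurrence count
#'
#' Bins the per-sample occurrence count X of a clonotype into the standard
#' expansion categories: single (X = 1), small (1 < X <= 5), medium
#' (5 < X <= 20), large (20 < X <= 100) and hyperexpanded (100 < X <= 500).
#' Counts above 500 fall outside the printed intervals and are mapped to
#' hyperexpanded with a warning rather than under-calling expansion.
#'
#' @param X Integer vector of clone occurrence counts (>= 1).
#' @return Factor with ordered levels single < small < medium < large <
#'   hyperexpanded.
#' @export
classify_expansion <- function(X) {
  if (any(X < 1) || any(X != round(X))) stop("X must be integer counts >= 1")
  if (any(X > 500))
    warning(sum(X > 500), " count(s) exceed 500; binned as hyperexpanded")
  cut(pmin(X, 500), breaks = c(0, 1, 5, 20, 100, 500),
      labels = c("single", "small", "medium", "large", "hyperexpanded"),
      ordered_result = TRUE)
}

#' chao1 nonparametric richness estimator
#'
#' Asymptotic species-richness estimate from singleton and doubleton counts:
#' `S_obs + f1^2 / (2 f2)` when doubletons exist, and the bias-corrected form
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` when `f2 = 0`. An empty repertoire
#' yields 0.
#'
#' @param counts Positive integer vector of clone sizes.
#' @return data.frame with `S_obs`, `f1`, `f2`, `chao1`.
#' @export
chao1 <- function(counts) {
  if (length(counts) == 0)
    return(data.frame(S_obs = 0L, f1 = 0L, f2 = 0L, chao1 = 0))
  if (any(counts < 1) || any(counts != round(counts)))
    stop("counts must be positive integers")
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  est <- if (f2 > 0) s_obs + f1^2 / (2 * f2)
         else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  data.frame(S_obs = s_obs, f1 = f1, f2 = f2, chao1 = est)
}

#' Per-sample repertoire diversity
#'
#' chao1 richness of each sample's repertoire, pooling clone counts across
#' T-cell subsets (repertoire-level diversity).
#'
#' @param clonotypes Clonotype table (`sample_id`, `cell_count`).
#' @return data.frame with one row per sample: `sample_id`, `S_obs`, `f1`,
#'   `f2`, `chao1`.
#' @export
diversity_by_sample <- function(clonotypes) {
  stopifnot(all(c("sample_id", "cell_count") %in% names(clonotypes)))
  per <- lapply(split(clonotypes$cell_count, clonotypes$sample_id), chao1)
  out <- do.call(rbind, per)
  out <- cbind(sample_id = names(per), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Expanded-clonotype fraction per T-cell subset
#'
#' For each sample and subset, the fraction of clonotype-bearing cells that
#' belong to expanded clones (X > 1). With `unit = "clones"` the fraction is
#' computed over clonotypes instead of cells.
#'
#' @param clonotypes Clonotype table (`sample_id`, `subset`, `cell_count`).
#' @param unit `"cells"` (default) or `"clones"`.
#' @return data.frame: `sample_id`, `subset`, `n_cells`, `n_clones`,
#'   `fraction_expanded`.
#' @export
expanded_fraction_by_subset <- function(clonotypes, unit = c("cells", "clones")) {
  unit <- match.arg(unit)
  stopifnot(all(c("sample_id", "subset", "cell_count") %in% names(clonotypes)))
  key <- interaction(clonotypes$sample_id, clonotypes$subset, drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(clonotypes)), key), function(ix) {
    x <- clonotypes$cell_count[ix]
    frac <- if (unit == "cells") sum(x[x > 1]) / sum(x) else mean(x > 1)
    data.frame(sample_id = clonotypes$sample_id[ix[1]],
               subset = clonotypes$subset[ix[1]],
               n_cells = sum(x), n_clones = length(x),
               fraction_expanded = frac, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare expanded fractions between progression groups
#'
#' Reshapes the per-sample, per-subset expanded fractions into a samples x
#' subsets matrix and delegates to [compare_groups()] (unpaired t test with
#' BH correction and the joint P/FDR significance rule).
#'
#' @param fractions Output of [expanded_fraction_by_subset()].
#' @param meta Sample metadata (see [compare_groups()]).
#' @param timepoint `"pre"` or `"post"`.
#' @param ... Passed to [compare_groups()].
#' @return A [compare_groups()] result, one row per subset.
#' @export
compare_expansion <- function(fractions, meta, timepoint = c("post", "pre"), ...) {
  timepoint <- match.arg(timepoint)
  samples <- sort(unique(fractions$sample_id))
  subsets <- sort(unique(fractions$subset))
  m <- matrix(NA_real_, length(samples), length(subsets),
              dimnames = list(samples, subsets))
  m[cbind(match(fractions$sample_id, samples),
          match(fractions$subset, subsets))] <- fractions$fraction_expanded
  compare_groups(m, meta, timepoint = timepoint, ...)
}
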