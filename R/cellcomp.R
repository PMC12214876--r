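#' Quality-control filter for annotated cells
#'
#' Removes low-quality cells: those with fewer than `min_genes` detected
#' genes, and those with more than `max_pct_mito` percent of reads mapping to
#' mitochondrial genes. Boundary cells (exactly `min_genes` genes, or exactly
#' `max_pct_mito` percent mitochondrial) are retained. Input order is
#' preserved; the per-reason removal counts are attached as the `qc_log`
#' attribute and reported via `message()`.
#'
#' @param cells data.frame with at least `n_genes` and `pct_mito` columns.
#' @param min_genes Minimum detected genes to keep a cell (default 500).
#' @param max_pct_mito Maximum mitochondrial percentage to keep (default 10).
#' @return The filtered data.frame with attribute `qc_log`.
#' @export
qc_filter <- function(cells, min_genes = 500, max_pct_mito = 10) {
  stopifnot(all(c("n_genes", "pct_mito") %in% names(cells)))
  low_genes <- cells$n_genes < min_genes
  high_mito <- cells$pct_mito > max_pct_mito
  keep <- !low_genes & !high_mito
  out <- cells[keep, , drop = FALSE]
  log <- list(n_input = nrow(cells), n_kept = sum(keep),
              n_low_genes = sum(low_genes), n_high_mito = sum(high_mito))
  message(sprintf("qc_filter: kept %d/%d cells (%d below %d genes, %d above %.1f%% mito)",
                  log$n_kept, log$n_input, log$n_low_genes, min_genes,
                  log$n_high_mito, max_pct_mito))
  attr(out, "qc_log") <- log
  out
}

#' Per-sample cell-type proportions
#'
#' Computes, for each sample, the fraction of cells carrying each label at
#' the requested granularity, after removing excluded labels (e.g. CD138+
#' plasma-cell and red-blood-cell clusters). Every row sums to 1. Samples
#' left with zero cells after exclusion are dropped with a warning.
#'
#' @param cells Annotated cell data.frame (`sample_id` plus the label column).
#' @param level `"subcluster"` or `"lineage"`: which label column to tally.
#' @param exclude Character vector of labels to remove before normalizing.
#' @return Numeric matrix, samples x cell types, rows summing to 1.
#' @export
compute_proportions <- function(cells, level = c("subcluster", "lineage"),
                                exclude = character()) {
  level <- match.arg(level)
  stopifnot(all(c("sample_id", level) %in% names(cells)))
  all_samples <- unique(cells$sample_id)
  lab <- cells[[level]]
  keep <- !(lab %in% exclude)
  cells <- cells[keep, , drop = FALSE]
  lab <- lab[keep]
  tab <- table(factor(cells$sample_id, levels = all_samples), lab)
  totals <- rowSums(tab)
  if (any(totals == 0)) {
    warning("dropping samples with zero cells after exclusion: ",
            paste(rownames(tab)[totals == 0], collapse = ", "))
    tab <- tab[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  props <- sweep(unclass(tab), 1, totals, "/")
  props <- matrix(props, nrow = nrow(tab), dimnames = dimnames(tab))
  names(dimnames(props)) <- NULL
  props
}

pooled_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (sd(c(x - mean(x), y - mean(y))) == 0) {
    # both groups internally constant: t statistic is 0/0 when means agree
    return(list(p.value = if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0,
                statistic = 0))
  }
  tt <- t.test(x, y, var.equal = TRUE)
  list(p.value = tt$p.value, statistic = unname(tt$statistic))
}

#' Compare cell-type proportions between the two progression groups
#'
#' For each column of a per-sample feature matrix (proportions, ratios or
#' expansion fractions), runs a two-sided unpaired Student's t test (pooled
#' variance; `test = "wilcox"` switches to a rank-sum test) between the two
#' groups at one timepoint, then applies Benjamini-Hochberg FDR correction
#' across columns. A comparison is flagged significant under the joint rule
#' `p <= 0.05` and `FDR <= 0.25`. Both group means and medians are reported;
#' the test operates on the per-sample values.
#'
#' @param props Numeric matrix, rows named by `sample_id`.
#' @param meta Sample metadata with `sample_id`, `timepoint` and the grouping
#'   column.
#' @param timepoint `"pre"` or `"post"`.
#' @param group_col Name of the grouping column in `meta` (two levels).
#' @param test `"t"` (default) or `"wilcox"`.
#' @return data.frame with one row per column of `props`: group means and
#'   medians, `p_value`, `fdr`, `significant`, and per-group sample counts.
#' @export
compare_groups <- function(props, meta, timepoint = c("post", "pre"),
                           group_col = "group", test = c("t", "wilcox")) {
  timepoint <- match.arg(timepoint)
  test <- match.arg(test)
  stopifnot(all(c("sample_id", "timepoint", group_col) %in% names(meta)))
  sel <- meta[meta$timepoint == timepoint & meta$sample_id %in% rownames(props), ]
  groups <- sort(unique(sel[[group_col]]))
  if (length(groups) != 2)
    stop("expected exactly 2 groups in column '", group_col, "', found ",
         length(groups))
  idx <- split(sel$sample_id, sel[[group_col]])
  for (g in groups) {
    if (length(idx[[g]]) < 2)
      stop("group '", g, "' has fewer than 2 samples at timepoint '",
           timepoint, "'")
  }
  x1 <- props[idx[[groups[1]]], , drop = FALSE]
  x2 <- props[idx[[groups[2]]], , drop = FALSE]
  res <- lapply(colnames(props), function(ctype) {
    a <- x1[, ctype]; b <- x2[, ctype]
    n1 <- sum(!is.na(a)); n2 <- sum(!is.na(b))
    if (n1 < 2 || n2 < 2) {
      return(data.frame(cell_type = ctype, mean_group1 = mean(a, na.rm = TRUE),
                        mean_group2 = mean(b, na.rm = TRUE),
                        median_group1 = median(a, na.rm = TRUE),
                        median_group2 = median(b, na.rm = TRUE),
                        n_group1 = n1, n_group2 = n2, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    p <- if (test == "t") pooled_t_test(a, b)$p.value
         else wilcox.test(a[!is.na(a)], b[!is.na(b)], exact = FALSE)$p.value
    data.frame(cell_type = ctype, mean_group1 = mean(a, na.rm = TRUE),
               mean_group2 = mean(b, na.rm = TRUE),
               median_group1 = median(a, na.rm = TRUE),
               median_group2 = median(b, na.rm = TRUE),
               n_group1 = n1, n_group2 = n2, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$significant <- !is.na(out$p_value) & out$p_value <= 0.05 & out$fdr <= 0.25
  attr(out, "groups") <- groups
  attr(out, "timepoint") <- timepoint
  out
}

#' Per-sample lineage ratio
#'
#' Ratio of summed numerator proportions to summed denominator proportions
#' (e.g. B to T/NK cells). Samples with a zero denominator yield `NA` with a
#' warning.
#'
#' @param props Proportion matrix (samples x cell types).
#' @param numerator,denominator Disjoint sets of column labels.
#' @return Named numeric vector of per-sample ratios.
#' @export
lineage_ratio <- function(props, numerator, denominator) {
  if (length(intersect(numerator, denominator)))
    stop("numerator and denominator labels must be disjoint")
  missing <- setdiff(c(numerator, denominator), colnames(props))
  if (length(missing))
    stop("labels not present in the proportion matrix: ",
         paste(missing, collapse = ", "))
  num <- rowSums(props[, numerator, drop = FALSE])
  den <- rowSums(props[, denominator, drop = FALSE])
  ratio <- num / den
  if (any(den == 0)) {
    warning(sum(den == 0), " sample(s) with zero denominator; ratio set to NA")
    ratio[den == 0] <- NA_real_
  }
  ratio
}

#' Aggregate proportion columns into coarser groups
#'
#' Sums proportion columns according to a named list of label groups (e.g.
#' [flow_lineage_groups()]), producing a matrix comparable to an aggregated
#' flow-panel view.
#'
#' @param props Proportion matrix.
#' @param groups Named list: output column -> input column labels.
#' @return Matrix with one column per group present in `props`.
#' @export
aggregate_lineages <- function(props, groups) {
  cols <- lapply(groups, intersect, colnames(props))
  cols <- cols[lengths(cols) > 0]
  out <- vapply(cols, function(cc) rowSums(props[, cc, drop = FALSE]),
                numeric(nrow(props)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(rownames(props), names(cols)))
  rownames(out) <- rownames(props)
  out
}

#' Concordance between flow-panel and single-cell lineage proportions
#'
#' Pearson correlation, per lineage, between flow-panel percentages and
#' single-cell proportions over paired samples.
#'
#' @param flow data.frame with `sample_id` and lineage columns in percent
#'   (0-100).
#' @param sc_props Single-cell proportion matrix (fractions; rows are
#'   samples) with matching lineage columns.
#' @param lineages Lineage labels to correlate (default: all shared columns).
#' @return Named numeric vector of Pearson r per lineage.
#' @export
flow_concordance <- function(flow, sc_props, lineages = NULL) {
  stopifnot("sample_id" %in% names(flow))
  shared_samples <- intersect(flow$sample_id, rownames(sc_props))
  if (length(shared_samples) < 3) stop("fewer than 3 paired samples")
  if (is.null(lineages))
    lineages <- intersect(setdiff(names(flow), "sample_id"), colnames(sc_props))
  missing <- setdiff(lineages, intersect(names(flow), colnames(sc_props)))
  if (length(missing))
    stop("lineages absent from one of the tables: ", paste(missing, collapse = ", "))
  fi <- flow[match(shared_samples, flow$sample_id), , drop = FALSE]
  vapply(lineages, function(l) {
    cor(fi[[l]] / 100, sc_props[shared_samples, l])
  }, numeric(1))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the two-sided p-value by hypergeometric enumeration using the
#' point-probability method: the sum of probabilities of all tables (with the
#' observed margins) no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
categorical_association <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("a 2x2 table is required")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  m <- sum(table[1, ])          # row 1 total
  n <- sum(table[2, ])          # row 2 total
  k <- sum(table[, 1])          # column 1 total
  x_obs <- table[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
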