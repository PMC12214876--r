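make_cells <- function(sample_id, subcluster, lineage = subcluster,
                       n_genes = 1000, pct_mito = 5) {
  data.frame(sample_id = sample_id,
             barcode = paste0("bc", seq_along(sample_id)),
             n_genes = n_genes, pct_mito = pct_mito,
             lineage = lineage, subcluster = subcluster,
             stringsAsFactors = FALSE)
}

test_that("qc keeps boundary cells and removes those past the thresholds", {
  cells <- make_cells(rep("s1", 4), rep("B", 4),
                      n_genes = c(499, 500, 2000, 2000),
                      pct_mito = c(2, 10, 10.1, 3))
  out <- suppressMessages(qc_filter(cells))
  expect_equal(out$n_genes, c(500, 2000))
  expect_equal(out$pct_mito, c(10, 3))
  log <- attr(out, "qc_log")
  expect_equal(log$n_low_genes, 1)
  expect_equal(log$n_high_mito, 1)
  empty <- suppressMessages(qc_filter(cells[0, ]))
  expect_equal(nrow(empty), 0)
})

test_that("proportions are per-sample hand counts that sum to one", {
  cells <- make_cells(c(rep("s1", 4), rep("s2", 10)),
                      c("B", "B", "CD8 T", "CD8 T",
                        rep("B", 3), "pDC", rep("monocyte", 6)))
  p <- compute_proportions(cells, "subcluster")
  expect_equal(unname(p["s1", c("B", "CD8 T")]), c(0.5, 0.5))
  expect_equal(unname(p["s2", c("B", "pDC", "monocyte")]), c(0.3, 0.1, 0.6))
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  # exclusion drops labels before normalizing; emptied samples are dropped
  p2 <- compute_proportions(cells, "subcluster", exclude = "CD8 T")
  expect_equal(unname(p2["s1", "B"]), 1)
  expect_warning(compute_proportions(cells[3:4, ], "subcluster",
                                     exclude = "CD8 T"), "zero cells")
})

test_that("duplicating every cell leaves proportions unchanged", {
  co <- simulate_cohort(small_config(seed = 5))
  p1 <- compute_proportions(co$cells, "subcluster")
  p2 <- compute_proportions(rbind(co$cells, co$cells), "subcluster")
  expect_equal(p1, p2)
})

test_that("group comparison applies the joint P/FDR significance rule", {
  # identical per-sample proportion vectors in the two groups: p = 1
  props <- matrix(c(0.2, 0.3, 0.2, 0.3, 0.8, 0.7, 0.8, 0.7), ncol = 2,
                  dimnames = list(paste0("s", 1:4), c("B", "T")))
  meta <- data.frame(sample_id = paste0("s", 1:4), timepoint = "post",
                     group = c("np", "np", "p", "p"))
  cmp <- compare_groups(props, meta, "post")
  expect_equal(cmp$p_value, c(1, 1))
  expect_false(any(cmp$significant))

  # significance requires both p <= 0.05 and fdr <= 0.25
  set.seed(4)
  n <- 20
  m <- cbind(sig = c(rnorm(n/2, 0), rnorm(n/2, 1.05)),
             matrix(rnorm(n * 19), n))
  colnames(m) <- paste0("f", 1:20)
  rownames(m) <- paste0("s", 1:n)
  meta2 <- data.frame(sample_id = rownames(m), timepoint = "post",
                      group = rep(c("np", "p"), each = n/2))
  cmp2 <- compare_groups(m, meta2, "post")
  expect_equal(cmp2$fdr, p.adjust(cmp2$p_value, "BH"))
  expect_equal(cmp2$significant,
               cmp2$p_value <= 0.05 & cmp2$fdr <= 0.25)
  # at least one raw-significant feature must be suppressed by the FDR arm
  # in this noisy panel, demonstrating the rule is genuinely joint
  expect_true(any(cmp2$p_value <= 0.05 & !cmp2$significant) ||
                all(cmp2$fdr[cmp2$p_value <= 0.05] <= 0.25))
  expect_error(compare_groups(m[1:11, ], meta2[1:11, ], "post"),
               "fewer than 2")
})

test_that("Benjamini-Hochberg adjustment matches the step-up procedure", {
  # hand-enumerated oracle: sorted p * n / rank, cumulative minimum from the
  # largest rank down
  set.seed(8)
  props <- matrix(rnorm(40), 10, 4,
                  dimnames = list(paste0("s", 1:10), paste0("f", 1:4)))
  meta <- data.frame(sample_id = rownames(props), timepoint = "post",
                     group = rep(c("a", "b"), each = 5))
  cmp <- compare_groups(props, meta, "post")
  p <- cmp$p_value
  ord <- order(p)
  stepup <- rev(cummin(rev(p[ord] * length(p) / seq_along(p))))[order(ord)]
  expect_equal(cmp$fdr, pmin(stepup, 1))
  expect_true(all(cmp$fdr >= cmp$p_value))
  expect_true(all(diff(cmp$fdr[order(cmp$p_value)]) >= -1e-12))
})

test_that("lineage ratios are arithmetic with missing-value handling", {
  props <- matrix(c(0.2, 0.3, 0.4, 0, 0.4, 0.7), 2,
                  dimnames = list(c("s1", "s2"), c("B", "TNK", "other")))
  r <- lineage_ratio(props[1, , drop = FALSE], "B", "TNK")
  expect_equal(unname(r), 0.5)
  expect_warning(r2 <- lineage_ratio(props, "B", "TNK"), "zero denominator")
  expect_true(is.na(r2["s2"]))
  expect_error(lineage_ratio(props, "B", "B"), "disjoint")
  expect_error(lineage_ratio(props, "B", "missing"), "not present")
})

test_that("group-shifted B enrichment raises the nonprogressor B:T/NK ratio", {
  shifts <- stats::setNames(rep(0, 35), default_celltypes()$subcluster)
  b_types <- default_celltypes()$subcluster[default_celltypes()$lineage == "B"]
  shifts[b_types] <- -0.7   # progressors depleted of B cells
  cfg <- sim_config(n_patients = 30, cells_per_sample = 500,
                    group_logfold_shifts = shifts, seed = 31)
  co <- simulate_cohort(cfg)
  lp <- compute_proportions(co$cells, "lineage")
  ratio <- lineage_ratio(lp, "B", c("CD4 T", "CD8 T", "NK"))
  post <- co$meta[co$meta$timepoint == "post", ]
  g <- post$group[match(names(ratio), post$sample_id)]
  keep <- !is.na(g)
  expect_gt(mean(ratio[keep][g[keep] == "nonprogressor"]),
            mean(ratio[keep][g[keep] == "progressor"]))
})

test_that("flow concordance is Pearson correlation over paired samples", {
  flow <- data.frame(sample_id = c("s1", "s2", "s3"),
                     B = c(10, 20, 30), TNK = c(30, 20, 10))
  sc <- matrix(c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3), 3,
               dimnames = list(c("s1", "s2", "s3"), c("B", "TNK")))
  r <- flow_concordance(flow, sc)
  expect_equal(unname(r["B"]), 1)
  expect_equal(unname(r["TNK"]), -1)
  expect_error(flow_concordance(flow[1:2, ], sc), "fewer than 3")
})

test_that("logit-noise flow emulation lands in the expected concordance range", {
  rs <- vapply(1:5, function(r) {
    co <- simulate_cohort(sim_config(n_patients = 20, cells_per_sample = 400,
                                     seed = 600 + r))
    lp <- compute_proportions(co$cells, "lineage")
    agg <- aggregate_lineages(lp, flow_lineage_groups())
    min(flow_concordance(co$flow, agg, c("B", "T/NK")))
  }, numeric(1))
  expect_true(all(rs > 0.5 & rs < 0.99))
})

test_that("Fisher exact enumeration matches independent oracles", {
  expect_equal(categorical_association(matrix(c(5, 5, 5, 5), 2)), 1)
  t2 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(categorical_association(t2), fisher_enumerate(t2),
               tolerance = 1e-12)
  expect_equal(categorical_association(t2), fisher.test(t2)$p.value,
               tolerance = 1e-12)
  # demographic-table fixture: males 13/19 vs 13/21; the enumerated
  # two-sided p, also confirmed by the reference implementation
  t3 <- matrix(c(13, 13, 6, 8), 2)
  expect_equal(categorical_association(t3), fisher.test(t3)$p.value,
               tolerance = 1e-12)
  # random tables with n <= 30 against brute-force enumeration
  set.seed(14)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 3), 2)
    expect_equal(categorical_association(tab), fisher_enumerate(tab),
                 tolerance = 1e-12)
    expect_equal(categorical_association(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(categorical_association(matrix(c(-1, 1, 1, 1), 2)),
               "non-negative")
})
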