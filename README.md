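# immprog

Immune-microenvironment progression analysis for multiple myeloma after
autologous stem cell transplant (ASCT).

Some patients progress within months of transplant, others stay
progression-free for years. The annotated cellular composition of the
CD138-depleted bone marrow — measured per sample as cell-type proportions
from single-cell transcriptomics, cross-checked against clinical flow
cytometry — and the clonal structure of the T-cell receptor (TCR)
repertoire both carry prognostic signal. `immprog` is the statistical
pipeline for that setting, for translational immunologists and
biostatisticians working with annotated cell tables, clonotype tables and
progression outcomes:

* **Composition statistics** — cell QC (≥500 genes, ≤10% mitochondrial
  reads), per-sample proportion matrices, unpaired *t* comparisons between
  progressors and nonprogressors with Benjamini–Hochberg correction and the
  joint significance rule *p* ≤ 0.05 & FDR ≤ 0.25, B:T/NK lineage ratios,
  flow-panel concordance, Fisher exact tests for categorical clinical
  variables.
* **TCR repertoire** — clonotype aggregation, expansion bins on the
  occurrence count X (single X = 1; small 1 < X ≤ 5; medium 5 < X ≤ 20;
  large 20 < X ≤ 100; hyperexpanded 100 < X ≤ 500), chao1 richness
  S_obs + f1²/(2 f2), and per-subset expanded-cell fractions.
* **Survival machinery** — Kaplan–Meier, log-rank, Efron-tie Cox regression
  (all implemented in-package and oracle-tested against `survival`), and
  maximally selected survival cutpoints for the univariate "optimal forest".
* **The interaction risk model** — for each post-ASCT patient, all cell-type
  proportions (plus CD56bright/CD56dim NK ratio, chao1 diversity, age) and
  **all pairwise products** form the feature matrix; an L1-penalized Cox
  model (cyclic coordinate descent on the Efron partial likelihood,
  compiled core) is fitted once per leave-one-out fold with inner
  cross-validated λ; per-feature signed occurrence counts across the
  ensemble measure robustness; the highest-R² model (Cox–Snell on the
  partial likelihood) is selected, transferred to external cohorts through
  a many-to-one cell-type harmonization map without refitting, and
  evaluated by median / 80th-percentile hazard-score stratification with
  log-rank tests and rank-sum comparisons against clinical response and
  MRD status.
* **A seeded synthetic cohort generator** — `simulate_cohort()` emulates
  the study design (40 patients × pre/post samples, 35 subclusters with
  group-shifted Dirichlet composition, Weibull proportional-hazards
  progression, power-law TCR clone sizes concentrated in CD8 subsets, a
  noisy logit-scale flow view) and exposes the ground truth for recovery
  tests.

## Worked example

```r
library(immprog)

cfg    <- sim_config(seed = 1)          # study-scale synthetic cohort
cohort <- simulate_cohort(cfg)
cells  <- qc_filter(cohort$cells)
#> qc_filter: kept 372047/480000 cells (15299 below 500 genes, 95684 above 10.0% mito)

props <- compute_proportions(cells, "subcluster")
cmp   <- compare_groups(props, cohort$meta, timepoint = "post")
head(cmp[order(cmp$p_value), c(1:3, 8:10)], 3)
#>          cell_type mean_group1 mean_group2  p_value    fdr significant
#> 13 CD8 T exhausted     0.06399      0.1034 0.000791 0.0277        TRUE
#> 15    CD8 T memory     0.02359      0.0436 0.007000 0.1225        TRUE
#> 24            MAIT     0.00646      0.0165 0.021625 0.2523       FALSE
```

Group 1 is nonprogressors, group 2 progressors: exhausted and memory CD8 T
cells are significantly more abundant in progressors after transplant
(both arms of the joint rule pass), while MAIT cells clear the raw *p*
threshold but not the FDR arm. Expansion bins over the cohort's ~139,000
clonotypes:

```r
table(classify_expansion(cohort$clonotypes$cell_count))
#>        single         small        medium         large hyperexpanded
#>        102849         31903          3887           399            11
```

The full pipeline — QC → proportions → comparisons → ratios → TCR →
cutpoint forest → leave-one-out risk model — runs from one seeded
configuration and writes every stage's tables plus a manifest with a config
hash and per-file checksums:

```r
manifest <- run_pipeline(run_config(out_dir = "run1", sim = cfg, seed = 1))
manifest$model
#> $r2          0.617      (training pseudo-R2 of the selected model)
#> $n_nonzero   13         (retained main/interaction terms)
#> $strat_chisq 9.30       (log-rank chi-square, median split of out-of-fold scores)
#> $strat_p     0.00229
#> $n_high 18  $n_low 18
```

On this simulated cohort the leave-one-out hazard scores stratify patients
into equal-sized high/low-risk groups whose progression-free survival
separates at p ≈ 0.002, and the planted exhausted-T::stromal interaction is
among the retained terms.

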