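---
title: "Modeling post-transplant progression from the bone-marrow immune microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling post-transplant progression from the bone-marrow immune microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immprog)
```

## The scientific problem

After autologous stem cell transplant (ASCT) for multiple myeloma, some
patients progress within months while others remain progression-free for
years. The composition of the bone-marrow immune microenvironment — the
relative abundance of T-cell, B-cell, NK, dendritic, monocytic, progenitor
and stromal populations measured by annotated single-cell transcriptomics —
carries prognostic information, and so does the clonal structure of the
T-cell receptor (TCR) repertoire. `immprog` implements the full statistical
pipeline for this setting: cell-level quality control, per-sample
compositional statistics, TCR expansion and diversity metrics,
outcome-oriented cutpoint screening, and a sparse proportional-hazards risk
model built on cell-type *interactions*, evaluated by leave-one-out
cross-validation and transferable to external cohorts through a cell-type
harmonization map.

Because the data this kind of study uses are controlled-access, the package
ships a first-class synthetic cohort generator (`simulate_cohort()`) that
reproduces the *statistical structure* of such a cohort and exposes its
ground truth, so every stage can be exercised and validated end to end.

## Cohort simulation

`sim_config()` defaults encode the study design the pipeline targets:

* 40 patients, each with one pre- and one post-ASCT sample;
* 35 annotated subclusters (see `default_celltypes()`) with a realistic
  baseline composition; per-sample proportions are Dirichlet with
  concentration 60, giving between-sample variability typical of annotated
  single-cell fractions;
* a latent progression-risk group per patient (prior probability 0.5). The
  progressor-group Dirichlet mean is shifted multiplicatively on the log
  scale (`group_logfold_shifts`), defaulting to more exhausted and memory
  CD8 T cells and fewer B/myeloid progenitors, monocytes and pDCs in
  progressors — the direction and rough magnitude of the composition
  differences the comparison stage is designed to detect;
* 6,000 cells per sample drawn multinomially from the true proportions
  (about 480,000 cells per cohort), with negative-binomial detected-gene
  counts and Beta-distributed mitochondrial percentages so that a realistic
  fraction of cells fails QC;
* progression-free survival from a Weibull baseline (shape 1, scale 2,500
  days, administrative censoring at 1,800 days) under proportional hazards.

**Hazard coefficients are per standard deviation.** `beta_main`,
`beta_interactions` and `group_hazard_offset` act on within-cohort z-scored
features: a coefficient of 0.7 on `"A::B"` means e^0.7 ≈ 2-fold hazard per
SD of the product of proportions A and B. Raw proportion products are of
order 10⁻³ and their natural scale varies with the number of cell types, so
raw-scale coefficients would be meaningless across configurations; per-SD
coefficients make effect sizes interpretable and transferable.

TCR repertoires are generated per sample by filling each T subcluster's
cell capacity with clones whose sizes follow a discrete power law
(`clone_size_exponent`, default 3). The default implies that roughly 40% of
T cells sit in expanded clones (size > 1), which reproduces the expanded
fractions reported for post-transplant marrow (roughly 50–90% of CD8 cells
and a few percent of CD4 cells expanded) once expanded clones are assigned
96%/4% to CD8/CD4 pools (`cd8_expanded_frac`). When the preferred pool has
no subset with room for an expanded clone, the clone overflows to the other
pool; if both are full its cells become singletons. `expansion_shift`
(default 0.3) lowers the exponent for progressor post-ASCT samples,
producing heavier clone-size tails — more expansion — in progressors after
therapy.

The flow-panel emulation aggregates the true lineage proportions into
gate-level groups (`flow_lineage_groups()`) and adds Gaussian noise on the
logit scale (σ = 0.3), which keeps values in (0, 1) and yields
flow-vs-single-cell Pearson correlations in the 0.6–0.8 range typical of
cross-platform lineage comparisons.

What the generator does **not** emulate: transcript-level expression,
doublets and ambient RNA, batch and integration artifacts, clustering and
annotation error, informative dropout or non-administrative censoring, and
cross-sample (public) clones. Tests passing on simulated cohorts therefore
validate the statistical machinery, not robustness to annotation error.

## Composition statistics

`qc_filter()` removes cells with fewer than 500 detected genes or more than
10% mitochondrial reads; both thresholds are boundary-inclusive for kept
cells (exactly 500 genes or exactly 10% is kept) — the literal reading of
"fewer than" / "more than". `compute_proportions()` tallies per-sample
fractions at lineage or subcluster granularity after excluding unwanted
labels (e.g. CD138⁺ or red-blood-cell clusters in real data).

`compare_groups()` runs a two-sided **unpaired Student's t test** (pooled
variance) per cell type. The pooled test is the unmarked default for
"unpaired t test"; a rank-sum alternative is available via `test =
"wilcox"`. P values are Benjamini–Hochberg adjusted within one timepoint
and one granularity level, and a comparison is called significant only
under the joint rule *p* ≤ 0.05 **and** FDR ≤ 0.25. Group means and
medians are both reported; the test operates on the per-sample values.
`lineage_ratio()` (e.g. B to T/NK) propagates zero denominators as missing
values, which are excluded pairwise with a logged count.
`categorical_association()` gives the two-sided Fisher exact p by
hypergeometric point-probability enumeration.

## TCR repertoire statistics

Clonotypes are aggregated per sample (`aggregate_clonotypes()`; majority
subset vote, lexicographic tie-break) and binned by occurrence count X:
single (X = 1), small (1 < X ≤ 5), medium (5 < X ≤ 20), large
(20 < X ≤ 100), hyperexpanded (100 < X ≤ 500). Counts above 500 fall
outside the defined bins; they are mapped to hyperexpanded with a warning
because under-calling expansion is the worse failure. Repertoire richness
is chao1 on sample-level clone counts pooled across subsets:
S_obs + f1²/(2 f2), with the bias-corrected form S_obs + f1(f1−1)/(2(f2+1))
when no doubletons exist. `expanded_fraction_by_subset()` reports, per
sample and subset, the fraction of clonotype-bearing **cells** in expanded
clones (a clonotype-level variant is available via `unit = "clones"`).

## Survival machinery

`km_estimate()`, `logrank_test()` and `cox_fit()` are implemented
in-package (the reference `survival` package serves as an independent
oracle in the test suite only). Cox regression uses the **Efron tie
correction** — the standard default, and ties are common once survival
times are recorded in days — with Newton–Raphson, step-halving, Wald
intervals, and a monotone-likelihood guard that caps runaway coefficients
at |β| = 15 with a warning. Median survival that is never reached is
reported as `NA` with an explicit `median_reached` flag, never as infinity
arithmetic.

`optimal_cutpoint()` scans thresholds at midpoints between consecutive
sorted unique feature values, restricted to the 10th–90th percentile with
at least 5 patients per side (standard maximally-selected-statistic
practice), maximizing the log-rank statistic. Log-rank was chosen as the
selection statistic; for a binary split it coincides asymptotically with
the Cox score test. **The reported p value is not corrected for threshold
selection** — this matches how such forests are usually presented — and the
suite quantifies the resulting anti-conservatism under the null (empirical
rejection well above 5%). Because the argmax of the log-rank process
wobbles by a few order statistics on continuous markers, threshold-recovery
properties are tested on markers measured at 0.05 resolution, where the
candidate grid is coarse enough for "within one grid step" to be a
meaningful target.

## The interaction risk model

`build_features()` assembles, per post-ASCT patient (patients already
progressed at sampling are excluded upstream), the main covariates — all
cell-type proportions plus, when supplied, the CD56bright/CD56dim NK ratio,
chao1 TCR diversity and age — and **all pairwise products** of the main
covariates, computed on the raw scale and then z-scored (so with m mains
there are m + m(m−1)/2 columns). All covariates enter interactions
uniformly, age included: the alternative (age as main effect only) is a
configuration users can express by passing extras into the model matrix
themselves, but the uniform rule is the default because the feature set is
defined as "all pairwise interactions". The CD56 ratio uses a pseudocount
of half the smallest nonzero proportion when the denominator is zero.

`fit_l1_cox()` minimizes −(1/n)·ℓ_Efron(Xβ) + λ‖β‖₁ by cyclic coordinate
descent on the quadratic approximation of the partial likelihood
(working-response form with the diagonal of the Hessian), with warm starts
along a decreasing λ path, convergence when the largest coefficient change
falls below 10⁻⁷, and two path guards: descent stops once 99% of the null
partial-likelihood deviance is explained (a saturation guard for p ≫ n),
and if the solver fails to converge deep in the path the path is truncated
at the last converged penalty with a warning. The compiled core makes the
leave-one-out ensemble tractable; at λ = 0 the solver agrees with the
Newton–Raphson fit to well below 10⁻⁴, and KKT subgradient conditions hold
at 10⁻⁶ along the path.

`loocv_ensemble()` fits one model per held-out patient. Within each fold,
features are re-standardized using the training patients only, λ is chosen
by inner 5-fold cross-validated partial-likelihood deviance (the
Verweij–van Houwelingen subtraction form) with a fold assignment seeded by
the outer fold index, and the held-out patient is scored with that fold's
model and standardization. Nothing about the held-out patient — outcome or
features — influences the fold's fit, which the suite verifies by
perturbing a held-out outcome and checking the fold's model is
bit-identical. λ selection by deviance-minimizing inner cross-validation is
the unmarked default where no rule is specified. Across the ensemble the
package counts, per feature, the number of models with a positive and with
a negative coefficient — the occurrence statistic used to judge feature
robustness (a strong interaction appears with consistent sign in n/n
models).

`select_model()` scores the full training cohort with each fold's model and
picks the one with the highest pseudo-R², defined as Cox–Snell on the
partial likelihood, R² = 1 − exp(2(ℓ₀ − ℓ_model)/n); "R²" has no unique Cox
definition, so the choice is recorded in the model metadata. Ties break
toward sparser models; the all-zero model scores exactly 0.

`harmonize()` transfers the model to an external cohort without refitting:
source cell-type labels map (many-to-one, proportions summed) onto the
model's main covariates, interactions are recomputed from the harmonized
mains, and everything is standardized with the **training** parameters.
Model features with no source data are imputed at the training mean —
standardized value exactly 0 — so they contribute nothing to any score,
and they are listed in the output. `stratify_and_test()` splits at the
median of out-of-fold scores for training-cohort evaluation (near-equal
groups, e.g. 17/18 at n = 35) and at the 80th percentile for external
cohorts with few events; `hazard_group_test()` compares hazard scores
between clinical groups (response, sustained MRD negativity) by Wilcoxon
rank-sum, exact for combined n ≤ 20 without ties. Extreme outlying scores
are a plotting concern only; they are never excluded from tests.

## Numerical choices and degenerate inputs

* Proportions are fractions internally; percentages only at I/O boundaries,
  with the unit declared (`read_flow_csv()` refuses tables whose values
  contradict the declared unit).
* Identical group values give t = 0, p = 1 rather than an error; samples
  emptied by label exclusion, zero-denominator ratios, folds without
  events, and features without admissible cutpoints are dropped/skipped
  with warnings and logged counts.
* `simulate_survival()` uses the exact Weibull inversion
  T = scale·(−log U / e^lp)^(1/shape); `censor = 0` yields all-censored
  records.
* All randomness is locally seeded (`sim_config(seed = )`, seeded fold
  assignments); identical configurations reproduce byte-identical outputs
  and pipeline manifests record a config hash and per-file checksums.

## Problem sizes used by the test suite

The suite validates recovery at n = 200 patients × 10 replicate cohorts for
the planted-interaction and stratification properties, 1,000 null cohorts
for type-I calibration, 500 null replicates for prespecified-cutoff
calibration, 50 random instances for KKT/path properties, and study-scale
(40 × 2 × 6,000 cells) cohorts for repertoire and pipeline checks; these
sizes give stable pass/fail behavior at desk scale.

## Known limitations

* The lasso active set is not strictly monotone along the λ path —
  correlated features can swap in and out (observed in ~10% of random
  instances) even at exact KKT optimality; the occurrence counts are
  therefore reported per chosen λ, not claimed monotone.
* Sparse-model selection at n ≈ 35 with p ≈ 740 features is honest about
  its variance: on weak-signal cohorts every leave-one-out model can be
  null, in which case stratification is reported as unavailable rather
  than fabricated.
* Cutpoint p values are selection-biased by construction (documented
  above); the forest is a screening display, not a confirmatory test.
* The harmonization contract assumes the external cohort's labels can be
  mapped onto the training covariates; biological non-correspondence is
  out of scope.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_patients = 20, cells_per_sample = 1000, seed = 1)
manifest <- run_pipeline(run_config(out_dir = "run1", sim = cfg, seed = 1))
str(manifest$model)
```
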