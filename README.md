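# siristrat

Interpretable survival risk stratification for oropharyngeal head and neck
cancer from the **systemic inflammation response index**

> SIRI = (neutrophils × monocytes) / lymphocytes

computed from a routine pre-treatment blood count, together with Karnofsky
performance status (KPS), body-mass index and smoking history.

The package is aimed at biostatisticians who want to turn a flexible but
opaque random survival forest into a bedside-usable decision rule, and to
test that machinery end-to-end on synthetic cohorts with known ground
truth. It implements:

* a **random survival forest** workflow (log-rank splitting, 1000 trees,
  ensemble cumulative-hazard risk scores) with Harrell's concordance
  index, permutation variable importance, and IPCW time-dependent AUC;
* **forest-guided cutoff discovery** — the package's central algorithm.
  Every splitting rule on a continuous covariate is harvested from the
  forest; the kernel density of the split thresholds (node-size weighted)
  is compared against the kernel density of the covariate itself, and
  cutoffs are the local maxima of the density difference where the forest
  splits at least twice as densely as the covariate's own mass explains.
  Cutoffs isolating less than 10 % of training subjects are excluded;
* a **constrained survival decision tree** on the discretized covariates
  (depth ≤ 3, every leaf ≥ 40 subjects, log-rank splitting with a χ²
  stopping rule), whose leaves are merged into three ordered risk groups
  by iteratively joining the most similar adjacent survival curves;
* the published **parsimonious three-variable rule** as a reference
  artifact: SIRI ≥ 3.5 → worst group regardless of anything else;
  otherwise KPS ≤ 70 → worst group; otherwise ever-smokers form the
  intermediate and never-smokers the best group;
* a **synthetic cohort generator** (log-normal SIRI, banded KPS,
  never/former/current smoking, Weibull proportional hazards with planted
  threshold effects at SIRI = 3.5 and KPS = 70, exponential dropout) whose
  defaults emulate the published cohort's marginals and follow-up;
* the full **evaluation stack**: Kaplan–Meier with Greenwood errors,
  k-group log-rank, pairwise Cox hazard ratios with Holm–Bonferroni
  correction, 75th-percentile risk splits, calibration tables and
  cloglog-intercept recalibration, and random-forest imputation of missing
  covariates.

## Worked example

```r
library(siristrat)

res <- run_full(pipeline_config(seed = 2))

res$cutoffs$siri$cutoffs
#> [1] 3.476552
print(res$tree)
#> Risk tree: depth 2, 3 leaves, 3 groups
#>   IF siri in {low} AND smoking in {never} THEN group 1
#>   IF siri in {low} AND smoking not in {never} THEN group 2
#>   IF siri not in {low} THEN group 3
round(res$report$cindex, 3)
#> [1] 0.675
res$report$pairwise_hr[, c("comparison", "hr", "ci_low", "ci_high")]
#>   comparison   hr ci_low ci_high
#> 1     2 vs 1 1.41  0.873    2.29
#> 2     3 vs 1 6.63  3.477   12.64
#> 3     3 vs 2 4.37  2.538    7.53
res$report$truth_agreement
#> [1] 0.8888889
```

One call simulates a 600-patient cohort with a planted threshold structure,
splits it 70/30, imputes missing covariates within each partition, fits the
forest on the training partition, discovers cutoffs, grows and merges the
risk tree, and evaluates the stratification on the held-out test set. Here
the discovered SIRI cutoff (3.48) lands within 1 % of the planted 3.5; the
tree recovers the SIRI and smoking structure (the low-KPS stratum is too
small to be isolated under the leaf-size floor of 40 at this cohort size);
the three groups separate sharply on the test set (log-rank p ≈ 1e-11,
group 3 vs 1 hazard ratio 6.6), and 89 % of test patients land in their
planted risk group.

The individual stages are exported (`simulate_cohort()`, `split_cohort()`,
`rf_impute()`, `fit_rsf()`, `discover_cutoffs()`, `discretize_cohort()`,
`grow_risk_tree()`, `merge_leaves()`, `assign_groups()`,
`parsimonious_reference_tree()`, `km_estimate()`, `logrank_test()`,
`cox_pairwise_hr()`, …) and composable on any cohort table with columns
`id, siri, kps, bmi, smoking, time, event` (CSV via `read_cohort()` /
`write_cohort()`).

See `vignettes/siristrat-methods.Rmd` for the model, the algorithm's
numerical choices, what the generator does and does not emulate, and known
limitations.

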