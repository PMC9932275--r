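# idex — explainable consensus classification of invasive disease events

`idex` is an R package for clinicians and biostatisticians who model
**invasive disease events** (IDE: recurrence, contralateral invasive breast
cancer, second primary cancers) within 5- or 10-year horizons from routine
clinical features — and who need predictions they can *explain* and training
labels they can *trust*.

It implements, as a tested and reusable pipeline:

* an **iterative multi-classifier consensus procedure**: 20 rounds of
  stratified 5-fold cross-validation of four classifier families (random
  forest, RBF SVM, gradient boosted trees, Gaussian naive Bayes); a patient
  misclassified in ≥ 15 of 20 rounds by **all four** classifiers is a
  *confounding patient* and is removed; two iterations by default.
  Agreement is tracked per classifier pair with Cohen's
  κ = (p₀ − pₑ)/(1 − pₑ), reported as mean ± sd over rounds;
* **Boruta** shadow-feature selection (permuted copies as an importance
  null; binomial hit tests with Bonferroni correction) with nested
  per-training-fold selection frequencies and the ≥ 60 % retention rule;
* a **prevalence-derived decision threshold**: the positive-class fraction
  of the cohort (0.29-type values at 5 years, 0.49-type at 10 years); a
  score is called IDE iff it strictly exceeds the threshold;
* a from-scratch **Shapley-value explanation layer**: exact coalition
  enumeration
  φⱼ = Σ_{S⊆F∖{j}} |S|!(M−|S|−1)!/M! · [v(S∪{j}) − v(S)]
  with marginal masking against a training-set background, and a
  kernel-weighted linear surrogate (Shapley kernel
  π(z) = (M−1)/[C(M,|z|)·|z|·(M−|z|)]) constrained to local accuracy:
  base value + Σφ = model score;
* a **synthetic cohort generator** (28 mixed-type clinical features with
  the published integer encodings, correlated lymph-node counts, a
  near-constant HER2 indicator, MCAR missingness, latent-logistic labels
  and *planted* label flips as ground-truth confounders) so that every
  stage is testable without access to any private cohort.

The four classifier families and the Boruta loop are implemented inside the
package (C++ tree ensembles and SMO solver) because the target environment
provides no R implementations of them.

## Worked example

Generate a balanced 10-year-like cohort of 300 patients with 10 % planted
label flips, run the consensus procedure, and explain a patient:

```r
library(idex)

sch <- default_paper_schema()
ev <- setNames(numeric(28), names(sch))
ev[c("diameter", "er", "ki67", "metastatic_lymph_nodes", "age")] <-
  c(6, 6, 6, 6, -6)                     # a strongly separable world
cfg <- cohort_config(n_patients = 300, horizon = "10y",
                     confounder_fraction = 0.1, seed = 42,
                     effect_vector = ev)
gen <- generate_cohort(cfg)
gen$cohort
#> <idex_cohort> 300 patients, 28 features, horizon 10y
#>   IDE prevalence: 0.493; missing entries: 440

prevalence_threshold(gen$cohort$labels)
#> <decision_threshold> 148/300 = 0.4933

specs <- default_model_specs(RF = list(n_trees = 120),
                             XGB = list(n_estimators = 80, max_depth = 4),
                             SVM = list(max_sweeps = 25))
sel <- c("diameter", "er", "ki67", "metastatic_lymph_nodes", "age")
rep <- iterate_consensus(gen$cohort, specs, cv_plan(20, 5, master_seed = 42),
                         n_iterations = 2, selection = sel)
rep
#> <consensus_report> 2 iterations: removed 39 of 300 (13.0%), 261 kept
#>   iteration 1: removed 36 (20 IDE, 16 non-IDE)
#>   iteration 2: removed 3 (2 IDE, 1 non-IDE)
#>   mean kappa before -> after:
#>     RF-SVM    0.78 -> 0.80
#>     RF-XGB    0.88 -> 0.89
#>     RF-NB     0.77 -> 0.83
#>     SVM-XGB   0.75 -> 0.81
#>     SVM-NB    0.81 -> 0.81
#>     XGB-NB    0.72 -> 0.79

length(intersect(rep$confounding_ids, gen$truth$confounder_ids))
#> [1] 24    # of 30 planted flips
```

The removal counts mirror the published bookkeeping style ("removed 39 of
300, 20 IDE and 16 non-IDE"), inter-classifier agreement rises after
removal, and 24 of the 30 planted label flips are recovered. Explaining one
included patient with exact Shapley values:

```r
em <- impute(encode(gen$cohort))
x <- em$x[, sel]
inc <- match(rep$included_ids, rownames(x))
y_inc <- gen$cohort$labels[match(rep$included_ids, gen$cohort$patient_ids)]
model <- fit_model(model_spec("XGB", n_estimators = 80, max_depth = 4),
                   x[inc, ], y_inc, seed = 42)
explain_patients(model, x[inc, ], x[inc[1:2], ], method = "exact",
                 bg_k = 25, seed = 42)[[1]]
#> <explanation> P0001: base 0.4757 + sum(phi) 0.4235 = score 0.8993 (exact)
#>   metastatic_lymph_nodes       +0.4744
#>   er                           -0.1637
#>   diameter                     +0.1551
#>   age                          -0.0516
#>   ki67                         +0.0094
```

The base value 0.476 is the mean model score over the background (the
"no-information" prediction); positive φ (metastatic lymph nodes, tumor
diameter) pushed this patient's score above it, toward the IDE call at
0.899, and the attribution sums exactly to the score (local accuracy).

A full run — generation, nested Boruta selection frequencies, consensus,
performance distributions, global and per-patient attribution tables — is
one call (or `Rscript inst/cli/idex.R all --config run.yaml`):

```r
manifest <- run_pipeline(run_config(
  cohort = list(n_patients = 300, confounder_fraction = 0.1),
  out_dir = "idex_run", seed = 7))
```

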