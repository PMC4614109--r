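# elmqsar

Binary QSAR classification of aromatase inhibitors (and any similar
descriptor-table activity data) with the **efficient linear method (ELM)**:
a deliberately simple, fully interpretable classifier whose training doubles
as a built-in descriptor-importance estimator.

## Who this is for

Cheminformaticians who start from a compounds × molecular-descriptors table
(e.g. Dragon output) with activity labels or pIC50 potencies and want

* a transparent linear activity model instead of a black box,
* a ranking of which descriptors carry the activity signal,
* an evaluation protocol (repeated stratified 10-fold cross-validation)
  that reports mean ± sd performance.

The package does **not** compute molecular descriptors from structures; it
starts from the descriptor table.

## The method

Compounds are scored by a pure weighted sum over the M selected
descriptors (no intercept; descriptors are z-score standardized):

    f(C) = Σᵢ wᵢ xᵢ ,   i = 1..M

and classified against a threshold t derived from the class-mean scores:
active (class 1) when `f(C) < t`, inactive (class 2) otherwise (actives carry
the lower class code, so low scores indicate activity; ties go to inactive).
By default t is the midpoint of the two class-mean scores.

Training has four stages:

1. **Descriptor selection.** A Welch t-test prefilter (p < 0.001) removes
   descriptors with no marginal class signal; a binary-chromosome GA
   (population 100, mutation 0.03, ≤ 1000 generations) then searches subsets
   with fitness −AIC, where `AIC = n·ln(RSS/n) + 2(k+1)` from the OLS fit of
   the class codes on the k included descriptors. The **usage frequency** —
   how many of the 100 final chromosomes include a descriptor — is the
   importance measure (0 = worst, 100 = best); descriptors with usage ≥ 90
   form the model subset.
2. **Initialization.** Each weight is the closed-form univariate
   least-squares slope of the class code on that descriptor:
   `wᵢ = Σⱼ(xᵢⱼ−x̄ᵢ)(yⱼ−ȳ) / Σⱼ(xᵢⱼ−x̄ᵢ)²`.
3. **Refinement.** A real-coded GA (same population/mutation/generation
   settings; BLX-0.5 crossover, Gaussian mutation, elitism, the initial
   weights seeded into generation 0) maximizes a robust **Andrews' sine
   fitness** of the residuals, `−Σⱼ ρ(yⱼ − f(Cⱼ))` with
   `ρ(r) = a²(1−cos(r/a))` for `|r| ≤ πa` and `2a²` beyond (a = 1.339);
   plain least squares is available as an alternative fitness. Elitism plus
   the seeded chromosome guarantee the refined weights are never worse than
   the initialization under the fitness.
4. **Evaluation.** Accuracy, sensitivity, specificity (percent) and the
   Matthews correlation coefficient, under stratified 10-fold
   cross-validation repeated 10 times with per-run seeds, reported as
   per-run rows plus mean ± sd.

## Worked example

```r
library(elmqsar)

# synthetic descriptor table shaped like a curated inhibitor set:
# 180 compounds (81 active / 99 inactive), 100 descriptors, 5 informative
syn <- generate_synthetic(synthetic_config(n_compounds = 180, n_descriptors = 100,
                                           n_informative = 5, effect_size = 1.5,
                                           seed = 42))

sel <- select_descriptors_ga(syn$dataset, selection_config(seed = 42))
print(sel)
#> GA descriptor selection: 200 generations over 100 descriptors
#>   top usage: INF003=96, INF004=96, INF001=95, INF002=94, INF005=93
#>   selected (usage >= 90): INF003, INF004, INF001, INF002, INF005

model <- elm_train(syn$dataset, sel, config = optimizer_config(seed = 42))
print(model)
#> ELM model: 5 descriptors, threshold -0.03885 (midpoint)
#>   score: f(C) = sum_i w_i x_i; predict active (1) when f(C) < threshold
#>   training RSS: initial 501.6 -> optimized 442.7

cv <- kfold_cv(syn$dataset, elm_trainer(sel, optimizer_config()), k = 10, seed = 42)
print(cv)
#> 10-fold CV (seed 42)
#>   pooled:   Acc 94.44%  Sen 95.06%  Spec 93.94%  MCC 0.888  (tp=77 tn=93 fp=6 fn=4)
#>   averaged: Acc 94.41%  Sen 95.00%  Spec 94.00%  MCC 0.891
```

The selection found exactly the five planted informative descriptors (usage
93–96 of 100; every noise descriptor scores far lower), GA refinement
reduced the training residual sum of squares from 501.6 to 442.7, and the
cross-validated accuracy (94.4%) sits close to the Bayes accuracy of the
generating model. `predict(model, newdata)` returns 1/2 classes, or raw
scores with `type = "score"`; `save_elm_model()` / `load_elm_model()`
round-trip models through a flat text format.

For pIC50-valued data, `curate_by_activity()` first removes compounds of
intermediate potency (5 < pIC50 < 6 by default) and labels the remainder
active (pIC50 ≥ 6) or inactive (≤ 5). `run_pipeline()` composes all stages
from a single config with one master seed; a thin command-line front-end
with `simulate` / `curate` / `select` / `train` / `predict` / `cv` / `run`
subcommands ships in `inst/cli/elm.R`.

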