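---
title: "The efficient linear method: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The efficient linear method: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elmqsar)
```

## The problem and the model

Aromatase inhibitors (AIs) suppress estrogen synthesis and are a mainstay of
hormone-dependent breast-cancer therapy. Given a table of real-valued
molecular descriptors for a compound library together with binary activity
labels (active = 1, inactive = 2) or pIC50 potencies, we want a classifier
that is accurate *and* tells us which descriptors matter — the usual trade
between predictive machinery (SVMs, neural networks) and interpretability.

The efficient linear method commits to the simplest useful architecture: a
no-intercept weighted sum over a small selected descriptor set,

$$ f(C) = \sum_{i=1}^{M} w_i x_i, $$

compared to a scalar threshold $t$; a compound is called active when
$f(C) < t$. Because the class codes are 1 for active and 2 for inactive and
the score is fit to track the codes, low scores indicate activity. A score
exactly at the threshold is called inactive — the conservative tie-break.

All interpretability then lives in three places: which descriptors are in
the model, their weights, and the usage-frequency ranking produced as a side
effect of selection.

## Descriptor selection and the usage-frequency importance

Selection runs in two stages.

**Welch prefilter.** Each descriptor is tested for a marginal class-mean
difference with a two-sided unequal-variance t-test; descriptors with
$p \ge \alpha$ (default $\alpha = 0.001$) are removed before any subset
search. The t-test is per-descriptor and subset-independent, so running it
once as a filter — rather than folding it into the subset fitness — loses
nothing and removes most of the noise dimensions cheaply. We deliberately
use the unequal-variance form; nothing in the data model promises equal
within-class spreads.

**GA subset search.** A binary chromosome carries one bit per surviving
descriptor. Chromosome fitness is $-\mathrm{AIC}$ of the ordinary
least-squares fit (with intercept) of the class codes on the included
descriptors,

$$ \mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2(k+1), $$

so adding a descriptor must buy enough RSS reduction to pay its parameter
penalty. Regressing on the 1/2 codes keeps the selection criterion aligned
with the downstream weighted-sum model, which is also fit to the codes. The
GA uses rank-proportional selection, uniform crossover (rate 0.8), per-bit
mutation at 0.03, two elites, population 100 and at most 1000 generations —
the mutation/population/generation settings are the method's stated
defaults; the operator choices are standard simple-GA and all sit in
`selection_config()`. Chromosomes are repaired to keep at least one bit set;
an RSS floor of $10^{-12}$ guards $\ln 0$ on perfect fits, and collinear
subsets fall back to a tiny-ridge ($10^{-8}$) fit rather than failing.

**Usage frequency.** After the final generation, a descriptor's importance
is the number of final-population chromosomes that include it, an integer in
$[0, 100]$. Descriptors at or above `usage_cutoff` (default 90) become the
model subset. We count over the *final* population because, under elitism
and converged selection pressure, it concentrates on subsets the search
considers good; a cumulative count (available via `usage_mode`) mixes in the
random early generations and flattens the ranking. The cutoff of 90 is a
convention, not a law — on a new dataset, inspect the usage histogram before
trusting it. Prefiltered descriptors are reported with usage 0.

## Weight initialization and robust GA refinement

Each initial weight is the closed-form univariate least-squares slope of the
class code on that descriptor,

$$ w_i = \frac{\sum_j (x_{ij}-\bar x_i)(y_j-\bar y)}{\sum_j (x_{ij}-\bar x_i)^2}, $$

computed independently per descriptor. This ignores descriptor correlations
by construction — it is an initialization, not the final model.

Refinement is a real-coded GA over the weight vector, maximizing the negated
Andrews' sine loss of the residuals $r_j = y_j - f(C_j)$:

$$ \rho(r) = \begin{cases} a^2\,(1-\cos(r/a)), & |r| \le \pi a \\ 2a^2, & |r| > \pi a.\end{cases} $$

This bounded, redescending loss behaves like least squares for small
residuals ($\rho(r) \approx r^2/2$) but caps the influence of badly-fit
compounds, so a few activity outliers cannot drag the weights. The tuning
constant defaults to $a = 1.339$, the conventional 95%-Gaussian-efficiency
choice, and is exposed in `optimizer_config()`; as $a \to \infty$ the
fitness tends to $-\mathrm{RSS}/2$ (we compute $\rho$ as
$2a^2\sin^2(r/2a)$, which is the same function without the $1-\cos$
cancellation, so this limit holds numerically too). A plain sum-of-squares
fitness is selectable for comparison.

Search is confined to the box $w_i^{(0)} \pm h\,s_i$ with
$s_i = |w_i^{(0)}| + \overline{|w^{(0)}|}$ and $h = 5$ (an unbounded
real-coded GA is ill-posed; the pooled term keeps near-zero-initialized
weights searchable). Operators: rank-proportional selection, BLX-0.5 blend
crossover, per-gene Gaussian mutation (sd 10% of the box width) at rate
0.03, two elites, population 100, at most 1000 generations. The initial
weight vector is injected into generation 0, so with elitism the best-ever
fitness can never fall below the initialization's — a hard invariant the
tests assert. Residual-loss improvement does not *guarantee* a training-MCC
improvement (the loss is a surrogate for classification), and on
well-behaved synthetic data the refinement's MCC gain is real but modest;
the refined model is never worse in fitness and rarely worse in MCC.

## Threshold

With class-mean scores $\bar f_{\text{act}}$ and $\bar f_{\text{inact}}$,
the default threshold is their midpoint
$(\bar f_{\text{act}} + \bar f_{\text{inact}})/2$, which lies between the
two score distributions whenever they separate. The difference
$\bar f_{\text{act}} - \bar f_{\text{inact}}$ is retained as
`threshold_mode = "literal_difference"` for fidelity experiments; note that
this quantity is generally *outside* the score range (for a score tracking
codes 1 and 2 it is negative while scores straddle 1.5), so it is not a
sensible default — it exists so that the alternative reading of the rule can
be reproduced and compared, and its use is flagged loudly in the model file.

## Standardization and other numerical choices

Descriptors are z-scored (mean 0, sample sd 1) on the *training* data only;
the stored statistics are applied to validation or new data. Both the
closed-form slopes and the GA search box are scale-sensitive, so raw Dragon
descriptors spanning orders of magnitude would otherwise dominate the model
arbitrarily. Zero-variance descriptors are excluded (their slope is
undefined) and reported. Standardization can be switched off for data that
is already scaled.

Other fixed choices: curation removes the *open* interval
$(\text{low}, \text{high}) = (5, 6)$ of pIC50, keeping boundary compounds
(pIC50 = 6 → active, = 5 → inactive) — a deterministic rule chosen because
the boundary convention is otherwise unspecified; MCC is defined as 0 when
its denominator vanishes; CV folds are stratified by class so every fold
contains both classes (a requirement of the threshold computation, and
essential under class imbalance); both GAs stop early after 200 generations
without best-fitness improvement, treating the 1000-generation cap as a
ceiling rather than a prescription.

Every stochastic component takes an explicit seed, and `run_pipeline()`
derives all stage seeds from one master seed
(stage $k$ gets $16\,\text{seed} + k \bmod (2^{31}-1)$), so a run
configuration maps to results as a pure function; re-running a config
reproduces its artifacts byte for byte.

## Cross-validation protocol and selection leakage

`repeat_experiments()` reproduces the repeated-protocol reporting style:
$R = 10$ independent experiments, each a full training plus stratified
10-fold CV with its own seed, summarized as per-run rows and mean ± sample
sd, with the best run flagged by CV MCC. By default, descriptor selection is
performed *once* on the full data and reused across folds — this mirrors the
original protocol but leaks selection information into the CV estimate.
`elm_trainer(nested = TRUE)` instead re-runs selection inside every training
fold; expect nested CV estimates to be lower and more honest. Both modes are
first-class because the package is also used to study the protocol itself.

## What the synthetic generator does and does not emulate

`generate_synthetic()` plants a known truth: class labels with exact
deterministic counts (default 180 compounds, 81 active / 99 inactive),
informative descriptors drawn from class-conditional Gaussians whose means
differ by `effect_size` within-class sds (optionally equicorrelated), noise
descriptors as independent standard Gaussians, and optionally pIC50 values
with an intermediate band (default fraction 0.33) to exercise curation. The
defaults mirror a curated steroidal AI study: 180 compounds, 637 candidate
descriptors, a small informative block at effect size 1.0.

This is exactly the structure the linear score with a midpoint threshold can
represent, which is the point: parameter-recovery and separability tests
need a recoverable truth (the generator also reports the Bayes-optimal
accuracy $\Phi(\Delta/2)$, $\Delta$ the Mahalanobis class distance, as a
ceiling to compare against). Real descriptor tables are *not* like this:
heavy-tailed and discrete descriptors, block correlations across hundreds of
descriptors, label noise, and activity cliffs are all absent. Passing the
synthetic suite therefore demonstrates that the algorithms do what they
claim under their own assumptions — not that any particular real-data
accuracy will be achieved.

Tests and examples in this package run the generator at a few hundred
compounds and around a hundred descriptors with ten informative ones — large
enough that the t-test prefilter and GA selection operate in their intended
regime, small enough to iterate quickly; the full-size default (637
descriptors) is used by the reproduction script.

## Known limitations

* The selection fitness is linear-OLS AIC; descriptors informative only
  through interactions or nonlinearities will be missed.
* The refinement optimizes a residual loss, not MCC or AUC; small
  training-MCC regressions relative to the initialization are possible even
  as the fitness improves.
* The usage-frequency ranking is a population statistic of a converged GA,
  not a significance measure; it has no p-value and correlated informative
  descriptors share usage.
* `literal_difference` thresholds are provided for protocol fidelity, not
  recommended use.
* No probabilistic outputs, multi-class support, or descriptor computation
  from structures.
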