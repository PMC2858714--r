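---
title: "Assessing re-identification risk from small geographic areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing re-identification risk from small geographic areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdcArea)
```

## The problem

Health datasets routinely carry a geographic code — in Canada, often the
Forward Sortation Area (FSA), the first three characters of the postal
code. Individuals in small areas are easier to re-identify: the smaller
the population, the more likely someone is the *only* person in the area
with a given combination of demographic values. Data custodians therefore
suppress or aggregate records from areas deemed "too small". The question
this package operationalises is *how small is too small*, and it answers
it with population uniqueness: an area is too small, for a given release,
when the proportion of its residents who are unique on the dataset's
quasi-identifiers exceeds a threshold — 0% for public releases, 5% or 20%
for progressively more trusted recipients.

## Quasi-identifier models and MaxCombs

A *quasi-identifier* (qid) is a variable an adversary could plausibly know
(age, gender, ethnicity, marital status, ...). A *quasi-identifier model*
is a set of 2–5 of them; an *equivalence class* is the set of records
sharing one exact value combination; a class of size one is a unique
record. The model's **MaxCombs** value is the maximum possible number of
equivalence classes — the product of its variables' declared
response-category counts. MaxCombs depends only on how variables are
coded, not on their empirical distribution, which is what lets a model
built on census variables generalise to other demographic
quasi-identifiers with comparable MaxCombs.

The default scheme (`defaultQidScheme()`) declares 11 census-style
variables. Four of them (language, ethnic origin, religion, visible
minority) all capture ethnicity, so model enumeration treats them as a
single generic ethnicity variable among 8 distinct qids, and afterwards
expands every model containing the placeholder into one concrete model per
variant. Age and gender are classed *high utility*: every enumerated model
must contain at least one of them. Note the one model consisting of age
and gender alone — with no further sensitive variable — is deliberately
part of the enumeration; the counting identities (42 + 48 = 90 models with
both age and gender; 134 with only age; 134 with only gender; 358 total)
hold only with it included. Models are deduplicated and ordered by size
then lexicographic member names, so outputs are reproducible.

```{r enumerate}
models <- enumerateModels(defaultQidScheme())
nrow(models)
range(models$max_combs)
```

The category counts are *declared*, never inferred from data. Continuous
variables must be discretised before they can participate; a variable
without a finite category count has no MaxCombs.

## Estimating population uniqueness from a sample

Sample uniqueness does not equal population uniqueness: a person unique in
a 20% sample is often not unique among the full population. Two classical
devices bracket the problem before any estimation:

* the **pigeonhole bound** (`pigeonholeFlag()`): with population $N$ and
  at most $k = \mathrm{MaxCombs}$ classes, $N \le k$ guarantees a unique
  is *possible*, and some class must hold at least $\lceil N/k \rceil$
  people;
* the **uniform-allocation expectation**
  (`expectedNonuniqueUniform()`): under independent uniform assignment the
  expected non-unique fraction is $1 - (1 - 1/k)^{N-1}$ — e.g. 26% for
  $N = 15$, $k = 48$ — showing how conservative the "any possible unique"
  criterion is.

The estimator proper (`zayatzUniqueness()`) works from the sample
*spectrum* $f_j$ (number of sample classes of exactly $j$ records) at
sampling fraction $p$:

1. naive spectrum estimate $\hat P(F=j) = f_j / \sum_k f_k$ of the
   population class-size distribution;
2. binomial detection probability
   $P(f{=}1 \mid F{=}j) = j\,p\,(1-p)^{j-1}$ that a population class of
   size $j$ yields exactly one sampled record;
3. Bayes' rule for
   $\hat P(F{=}1 \mid f{=}1)$, the probability a sample unique is a
   population unique;
4. estimated population uniques
   $f_1 \cdot \hat P(F{=}1 \mid f{=}1) / p$, i.e. the expected count among
   sample uniques scaled up by the detection probability
   $P(f{=}1 \mid F{=}1) = p$; divided by $N$ and clipped to $[0,1]$.

Numerical and design choices, all visible in the API:

* **Binomial, not hypergeometric, subsampling** by default. At the area
  sizes this tool targets (hundreds to tens of thousands) the difference
  is negligible; an exact hypergeometric variant is available via
  `method = "hypergeometric"` and the test suite checks the two agree
  closely.
* **Missing qid values form their own category.** A record with an
  unrecorded value remains distinguishable from every observed value;
  merging it into an existing class would understate uniqueness, so the
  conservative choice is made.
* **Thresholds are strict**: $I_{05} = [\hat u > 0.05]$,
  $I_{20} = [\hat u > 0.20]$; exactly 5% is not flagged, and
  $I_{20} = 1 \Rightarrow I_{05} = 1$ always.
* **Per-area spectra.** Uniqueness is estimated from each area's own
  spectrum (one estimate per area × model), not from a pooled national
  spectrum — matching the per-area decision the tool must make.
* At $p = 1$ the estimator reduces exactly to sample uniqueness; with no
  sample uniques it returns 0 without further computation.

The estimator is known to over-estimate at small sampling fractions; at
the 20% fraction it is aimed at, the validation below measures its error
directly against exact ground truth.

## The risk models

One observation per (area × qid model) carries `POP` (area population),
`MaxCombs`, and the indicators. The logistic model

$$\mathrm{logit}(\pi) = b_0 + b_1\,\mathrm{POP_{cs}} +
  b_2\,\mathrm{MaxCombs_{cs}} +
  b_3\,\mathrm{POP_{cs}}\cdot\mathrm{MaxCombs_{cs}}$$

uses **centered** predictors (avoiding collinearity with the interaction)
**scaled by 10,000** (both variables are large; their product would
otherwise overflow the working range of the optimiser). The interaction
lets the MaxCombs–uniqueness relationship bend with area size instead of
fitting one model per area. Centering constants are computed from the
training data and serialised with the model; `publishedRiskModel()`, which
ships the published coefficient sets, *requires* the user to supply
centering constants because the ones used for the published fits are not
recoverable — silently fabricating them would change what the rule flags.

Most observations sit on one side of each threshold, so plain ML is
fragile here. Two corrections are implemented:

* **Down-sampling with prior correction** (`method = "downsample"`): keep
  every minority-class row, draw an equal-size seeded subsample of the
  majority class, fit, then subtract
  $\ln[((1-\tau)/\tau)\,(\bar y/(1-\bar y))]$ from the intercept, where
  $\tau$ is the full-data prevalence and $\bar y$ the balanced-sample
  prevalence (0.5 by construction). Only the intercept needs adjusting —
  balanced resampling leaves the slope structure intact.
* **King–Zeng** (`method = "kz"`): fit on the full data and subtract the
  small-sample bias term $(X'WX)^{-1}X'W\xi$ with
  $W = \mathrm{diag}(\hat\pi_i(1-\hat\pi_i))$,
  $Q = X(X'WX)^{-1}X'$, $\xi_i = \tfrac12 Q_{ii}(2\hat\pi_i - 1)$. The
  term vanishes as $n$ grows, so KZ converges to ML on large balanced
  data; with rare positives it reduces coefficient RMSE (both properties
  are tested).

**Influential observations** are removed in a single pass before final
fitting (`removeInfluential()`): standardized leave-one-out coefficient
changes (dfbetas) with the conventional $2/\sqrt n$ cutoff. The influence
diagnostic is a deliberate design choice — dfbetas targets exactly the
quantity we care about (coefficient distortion) — and on clean synthetic
data it removes only a few percent of rows, consistent with the removal
rates such models exhibit in practice.

**Decision rule**: an area is flagged when $\pi > 0.5$ (strictly; at the
0.5 cutoff this equals the sign of the logit). The cutoff is overridable
but 0.5 is the operational default throughout.

In this extreme-signal regime, fitted probabilities of numerically 0 or 1
are *expected*, not pathological; the fitter therefore does not treat that
condition as separation. Separation is flagged (with a warning, and in the
model's `fitInfo`) on non-convergence, runaway coefficients or a
degenerate information matrix, and coefficients are still returned. IRLS
runs with a tightened tolerance (1e-10) and up to 100 iterations.

## Evaluation

`crossValidate()` uses **stratified** 10-fold assignment — folds are
balanced within each class so rare positives appear in every fold; plain
decile splits can produce training folds with an empty class, which is a
fitting error, and stratification removes that failure mode by
construction. Rebalancing/correction happens inside each training split
only. Out-of-fold predictions are pooled: one confusion matrix at the 0.5
cutoff (sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), positive =
high risk), and AUC on the pooled probabilities via the Mann–Whitney rank
formulation with **midrank tie handling**, which preserves the
interpretation of AUC as the probability a random above-threshold
observation outscores a random below-threshold one, ties counting half.
With a fixed seed the entire run is bit-reproducible.

## The synthetic census generator

Restricted census microdata cannot ship with a package, so validation
rests on `generatePopulation()`:

* **Area sizes** drawn log-uniformly in `[200, 78457]` by default — the
  span of urban-FSA populations the risk models target — giving the
  right-skewed size distribution of real postal geography (many small
  areas, few large ones).
* **Category distributions** default to Zipf with exponent 1.2 rather than
  uniform: real demographic categories are strongly skewed (a few common
  values, a long tail), and that skew is what produces the unbalanced
  indicator regime the corrections exist for. Uniform and fully explicit
  per-variable probabilities are available.
* **Optional latent-class dependence** (k classes with mixing weights,
  per-class permutations of each variable's category probabilities)
  induces association between variables without changing marginal skew.
* A per-area 20% **simple random sample without replacement** plays the
  long form's role. Each area is seeded independently from the spec seed,
  so a given area's draw is stable when the number of areas changes.
* **Ground truth by exact counting** (`trueUniqueness()`), always: every
  estimator is measured against an enumeration of the generated
  population, never against another estimate.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: realistic joint demographic distributions
(education–income–age dependence beyond the generic latent-class device),
household structure, spatial autocorrelation between neighbouring areas,
and the census's own measurement quirks. The validation demonstrates that
the estimators and fitting machinery recover a known truth under
realistic marginal skew and size ranges; calibration on real census data
would still be needed before operational use of freshly fitted models.

## Validation problem sizes

The shipped validation suite uses: 30 areas of 1,000–20,000 people for
Zayatz recovery (mean absolute error ≤ 0.075 and Spearman ≥ 0.9 against
exact truth, tolerances fixed in advance against the exact-count oracle);
n = 50,000 observations for logistic parameter recovery (both corrections
inside their 95% CIs); 40 areas × 60 models for the cross-validated AUC
check (> 0.9); and 50 replicates of n = 5,000 for the rare-events RMSE
comparison. These sizes give stable verdicts at interactive runtimes while
exercising the full size range of the generator.

## Known limitations

* The Zayatz estimator's naive spectrum step biases upward when the
  sampling fraction is far below 20%; the package does not implement the
  Poisson–gamma (Bethlehem) alternative.
* The published coefficient sets are usable only with externally supplied
  centering constants, as discussed above; fitted models carry their own.
* MaxCombs ignores the empirical distribution of the variables by design;
  entropy-style refinements have historically not improved prediction, but
  that ceiling-effect argument is inherited, not re-verified here.
* Areas are treated independently; aggregation planning (merging small
  areas into larger ones) is out of scope, as is deriving category counts
  from raw data.
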