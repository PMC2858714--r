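# sdcArea

Deciding when a geographic area is **too small to disclose** in a health
dataset. Records from people living in small areas (in Canada, typically
indexed by the Forward Sortation Area, the first three characters of the
postal code) are easier to re-identify, and a common disclosure-control
action is to suppress all records from areas judged too small. `sdcArea`
implements a proportionate, model-based version of that judgement for data
custodians and disclosure-control analysts: instead of a fixed population
cutoff, an area is flagged when the estimated proportion of *unique*
individuals on the dataset's quasi-identifiers exceeds a chosen threshold
(0%, 5% or 20%).

## The method

For a set of quasi-identifiers (age, gender, ethnicity, ...), an
**equivalence class** is the group of records sharing one exact value
combination; a class of size one is a **unique** record. Population
uniqueness in an area is estimated from a sample (e.g. the 20% long-form
census sample) with the **Zayatz estimator**: writing `f_j` for the number
of sample classes of size `j` and `p` for the sampling fraction, the
probability that a sample unique is a population unique is obtained by
Bayes' rule from the naive spectrum estimate `P(F = j) ∝ f_j` and the
binomial detection probability `P(f = 1 | F = j) = j p (1 − p)^{j−1}`; the
estimated number of population uniques is `f_1 · P(F = 1 | f = 1) / p`.

Whether an area exceeds the 5% or 20% uniqueness threshold is then
predicted by a logistic **risk model** on two characteristics only: the
area population size `POP` and the quasi-identifier model's maximum number
of equivalence classes `MaxCombs` (the product of the variables'
response-category counts),

```
logit(π) = b0 + b1·POP_cs + b2·MaxCombs_cs + b3·POP_cs·MaxCombs_cs
```

with both predictors centered and scaled by 10,000. Because far more
observations fall on one side of a threshold than the other, fitting uses
rare-events techniques: down-sampling with an analytic prior correction of
the intercept, or the King–Zeng small-sample bias correction. Models are
evaluated by stratified 10-fold cross-validation (pooled confusion matrix
at a 0.5 cutoff, AUC on pooled probabilities). An area with predicted
probability above 0.5 is flagged and its records suppressed. The shipped
published coefficients — `(779.1, −37.35, 137.8, −6.5)` for the 5%
threshold and `(63.3, −6, 11.8, −1)` for 20% — can be applied directly via
`publishedRiskModel()` (centering constants must be supplied; see the
vignette).

Because the census microdata behind such models is restricted, the package
includes a **synthetic census generator**: multi-area categorical
populations with Zipf-skewed categories, a per-area 20% sample, and exact
ground-truth uniqueness, so every estimator and model can be validated
end-to-end against a known truth.

## Worked example

```r
library(sdcArea)

scheme <- defaultQidScheme()          # 11 census-style quasi-identifiers
models <- enumerateModels(scheme)     # all 2-5 qid models
nrow(models)                          # 358
min(models$max_combs)                 # 6   (gender x religion)

synth <- generatePopulation(populationSpec(nAreas = 20, seed = 42))
est <- uniquenessEstimates(sampleRecords(synth), c("age", "gender", "marital"),
                           popTable(synth), samplingFraction = 0.2)
head(est, 4)
#>   area n_sample   pop sample_uniqueness est_population_uniqueness I05 I20
#> 1 A001     9434 47171          0.000848                  3.13e-05   0   0
#> 2 A002    10776 53880          0.000278                  4.03e-06   0   0
#> 3 A003      221  1104          0.226244                  1.05e-01   1   0
#> 4 A004     5700 28502          0.002807                  1.70e-04   0   0
```

Area `A003` (about 1,100 residents) has an estimated 10.5% population
uniqueness on age × gender × marital status, so it exceeds the 5%
threshold (`I05 = 1`) but not the 20% one. Fitting and evaluating a 5%
risk model on the area × model observation table:

```r
mt  <- buildModelingTable(synth, models[models$size <= 3, ])
m05 <- fitRiskModel(mt, "I05", method = "downsample", seed = 1)
crossValidate(mt, "I05", "downsample", seed = 1)
#> EvalReport (pooled 10-fold CV)
#>   AUC         0.9968
#>   sensitivity 0.9495
#>   specificity 0.9908
#>   confusion  tp=432 fp=12 tn=1293 fn=23

suppressionReport(sampleRecords(synth), popTable(synth), m05,
                  scheme, c("age", "gender", "marital"))
#> SuppressionReport (5% threshold)
#>   areas flagged: 4 of 20
#>   records suppressed: 575 of 78560 (0.7%)
```

The report says that releasing this dataset under the 5% threshold would
require suppressing the records of 4 small areas — 0.7% of all records.

A thin command-line dispatcher over the same functions is installed at
`inst/cli/sdc-area.R` (subcommands `simulate`, `enumerate-models`,
`maxcombs`, `uniqueness`, `fit`, `evaluate`, `flag`, `suppress`).

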