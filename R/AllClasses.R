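#' @import methods
NULL

#' Quasi-identifier scheme
#'
#' A `QidScheme` declares the quasi-identifiers available for disclosure-risk
#' analysis: each variable's name, its number of response categories, and its
#' utility class (`"high_utility"` for variables an intruder almost certainly
#' knows, such as age and gender; `"sensitive"` for the rest). A group of
#' ethnicity-related variables (language, ethnic origin, religion, visible
#' minority in the default scheme) is represented in model enumeration by a
#' single generic ethnicity placeholder that is expanded into its concrete
#' variants.
#'
#' Category counts are declared, not derived from data: a scheme describes
#' how the variables are coded (e.g. age in 5-year bands gives 24 categories),
#' which fixes the maximum possible number of equivalence classes for any
#' model built from it.
#'
#' @slot variables data.frame with columns `name`, `n_categories`,
#'   `utility_class`, `ethnicity_group_member`.
#' @slot ethnicityVariants character vector naming the variables that stand
#'   in for the generic ethnicity placeholder during enumeration.
#' @slot genericName name used for the placeholder (default `"ethnicity"`).
#'
#' @seealso [defaultQidScheme()], [enumerateModels()], [maxCombs()]
#' @export
setClass("QidScheme",
  representation(
    variables = "data.frame",
    ethnicityVariants = "character",
    genericName = "character"
  )
)

setValidity("QidScheme", function(object) {
  v <- object@variables
  msgs <- character()
  needed <- c("name", "n_categories", "utility_class", "ethnicity_group_member")
  if (!all(needed %in% names(v))) {
    return(paste("variables must have columns:", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(v$name)) msgs <- c(msgs, "variable names must be unique")
  if (any(v$n_categories < 2)) {
    msgs <- c(msgs, "every quasi-identifier needs at least 2 response categories")
  }
  if (!all(v$utility_class %in% c("high_utility", "sensitive"))) {
    msgs <- c(msgs, "utility_class must be 'high_utility' or 'sensitive'")
  }
  if (!all(object@ethnicityVariants %in% v$name)) {
    msgs <- c(msgs, "every ethnicity variant must be a declared variable")
  }
  if (length(object@genericName) != 1L) {
    msgs <- c(msgs, "genericName must be a single string")
  }
  if (object@genericName %in% v$name) {
    msgs <- c(msgs, "the generic placeholder name must not collide with a variable")
  }
  if (length(msgs)) msgs else TRUE
})

#' Equivalence-class size spectrum
#'
#' The frequency-of-frequencies summary of one area's records under one
#' quasi-identifier model: `f[j]` is the number of equivalence classes
#' containing exactly `j` records. `f["1"]` is the number of sample uniques.
#'
#' @slot f named integer vector, names are class sizes `j`.
#' @slot nRecords total records summarised.
#' @slot nClasses number of distinct equivalence classes.
#'
#' @seealso [equivalenceSpectrum()], [sampleUniqueness()],
#'   [zayatzUniqueness()]
#' @export
setClass("EquivalenceSpectrum",
  representation(f = "integer", nRecords = "integer", nClasses = "integer")
)

setValidity("EquivalenceSpectrum", function(object) {
  f <- object@f
  msgs <- character()
  if (length(f)) {
    j <- suppressWarnings(as.integer(names(f)))
    if (anyNA(j) || any(j < 1L)) {
      return("names of f must be positive integer class sizes")
    }
    if (any(f < 0L)) msgs <- c(msgs, "class counts must be non-negative")
    if (sum(j * f) != object@nRecords) {
      msgs <- c(msgs, "sum of j * f[j] must equal nRecords")
    }
    if (sum(f) != object@nClasses) {
      msgs <- c(msgs, "sum of f[j] must equal nClasses")
    }
  } else if (object@nRecords != 0L || object@nClasses != 0L) {
    msgs <- c(msgs, "empty spectrum must have zero records and classes")
  }
  if (length(msgs)) msgs else TRUE
})

#' Logistic small-area risk model
#'
#' A fitted or published logistic model predicting whether an area's
#' population uniqueness exceeds a threshold (5% or 20%) from the area's
#' population size (`POP`) and the quasi-identifier model's maximum number of
#' equivalence classes (`MaxCombs`), with their interaction. Both predictors
#' are centered and scaled (by 10,000 by default) before entering the logit;
#' the centering constants are stored with the model so prediction applies
#' the exact same transformation.
#'
#' @slot thresholdLabel `"5%"` or `"20%"`.
#' @slot coef named numeric vector `(intercept, pop, maxcombs, interaction)`.
#' @slot popCenter,maxcombsCenter centering constants on the raw scale.
#' @slot scale divisor applied after centering (default 10,000).
#' @slot provenance `"fitted"` or `"published"`.
#' @slot vcov coefficient covariance matrix (published models carry a matrix
#'   of `NA`).
#' @slot fitInfo list of fit metadata (method, seed, prevalence, separation
#'   flag, ...).
#'
#' @seealso [fitRiskModel()], [publishedRiskModel()], [predictRisk()],
#'   [flagSmallArea()]
#' @export
setClass("LogitRiskModel",
  representation(
    thresholdLabel = "character",
    coef = "numeric",
    popCenter = "numeric",
    maxcombsCenter = "numeric",
    scale = "numeric",
    provenance = "character",
    vcov = "matrix",
    fitInfo = "list"
  )
)

setValidity("LogitRiskModel", function(object) {
  msgs <- character()
  if (!identical(names(object@coef),
                 c("intercept", "pop", "maxcombs", "interaction"))) {
    msgs <- c(msgs, "coef must be named (intercept, pop, maxcombs, interaction)")
  }
  if (!all(is.finite(object@coef))) msgs <- c(msgs, "coefficients must be finite")
  if (!object@thresholdLabel %in% c("5%", "20%")) {
    msgs <- c(msgs, "thresholdLabel must be '5%' or '20%'")
  }
  if (!object@provenance %in% c("fitted", "published")) {
    msgs <- c(msgs, "provenance must be 'fitted' or 'published'")
  }
  if (length(object@scale) != 1L || !is.finite(object@scale) ||
      object@scale <= 0) {
    msgs <- c(msgs, "scale must be a single positive number")
  }
  if (length(msgs)) msgs else TRUE
})

#' Synthetic census-like population
#'
#' A generated multi-area categorical population together with its per-area
#' simple random sample (emulating a long-form census sample), the area
#' population lookup table, and the generating specification. Ground-truth
#' population uniqueness is computed exactly from the `population` slot by
#' [trueUniqueness()].
#'
#' @slot population data.frame, one row per person: `area` plus one column
#'   per quasi-identifier (integer category codes).
#' @slot sample data.frame, the per-area sample drawn without replacement.
#' @slot popTable data.frame with columns `area`, `pop`.
#' @slot samplingFraction fraction sampled per area.
#' @slot scheme the [QidScheme] the variables were generated under.
#' @slot spec the generating [populationSpec()] list.
#'
#' @seealso [generatePopulation()], [trueUniqueness()],
#'   [buildModelingTable()]
#' @export
setClass("SyntheticPopulation",
  representation(
    population = "data.frame",
    sample = "data.frame",
    popTable = "data.frame",
    samplingFraction = "numeric",
    scheme = "QidScheme",
    spec = "list"
  )
)

setValidity("SyntheticPopulation", function(object) {
  msgs <- character()
  if (!all(c("area", "pop") %in% names(object@popTable))) {
    msgs <- c(msgs, "popTable needs columns area, pop")
  }
  if (object@samplingFraction <= 0 || object@samplingFraction > 1) {
    msgs <- c(msgs, "samplingFraction must be in (0, 1]")
  }
  if (nrow(object@sample) > nrow(object@population)) {
    msgs <- c(msgs, "sample cannot be larger than the population")
  }
  if (length(msgs)) msgs else TRUE
})

#' Cross-validation evaluation report
#'
#' Pooled 10-fold cross-validation results for a risk model: the confusion
#' matrix at the probability cutoff, sensitivity, specificity, and the AUC of
#' the pooled out-of-fold predicted probabilities. Positive = high risk =
#' uniqueness above the threshold.
#'
#' @slot auc area under the ROC curve of pooled predictions.
#' @slot sensitivity tp / (tp + fn).
#' @slot specificity tn / (tn + fp).
#' @slot confusion named integer vector `(tp, fp, tn, fn)`.
#' @slot folds per-fold metadata data.frame.
#' @slot seed seed that produced the fold assignment.
#'
#' @seealso [crossValidate()]
#' @export
setClass("EvalReport",
  representation(
    auc = "numeric",
    sensitivity = "numeric",
    specificity = "numeric",
    confusion = "integer",
    folds = "data.frame",
    seed = "integer"
  )
)

setValidity("EvalReport", function(object) {
  msgs <- character()
  if (!identical(names(object@confusion), c("tp", "fp", "tn", "fn"))) {
    msgs <- c(msgs, "confusion must be named (tp, fp, tn, fn)")
  }
  if (any(object@confusion < 0L)) msgs <- c(msgs, "confusion counts must be >= 0")
  if (object@auc < 0 || object@auc > 1) msgs <- c(msgs, "auc must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Suppression report
#'
#' The outcome of applying a threshold model (or the 0% any-unique rule) to a
#' dataset: which areas are flagged as too small, and what fraction of the
#' records would be suppressed if all records in flagged areas were withheld.
#'
#' @slot thresholdLabel `"0%"`, `"5%"` or `"20%"`.
#' @slot areas data.frame with one row per area: `area`, `n_records`,
#'   `probability` (NA under the 0% rule), `flagged`.
#' @slot recordsTotal,recordsSuppressed record counts.
#' @slot percentSuppressed `100 * recordsSuppressed / recordsTotal`.
#'
#' @seealso [suppressionReport()]
#' @export
setClass("SuppressionReport",
  representation(
    thresholdLabel = "character",
    areas = "data.frame",
    recordsTotal = "integer",
    recordsSuppressed = "integer",
    percentSuppressed = "numeric"
  )
)

setValidity("SuppressionReport", function(object) {
  msgs <- character()
  a <- object@areas
  if (!all(c("area", "n_records", "flagged") %in% names(a))) {
    msgs <- c(msgs, "areas needs columns area, n_records, flagged")
  } else {
    if (sum(a$n_records) != object@recordsTotal) {
      msgs <- c(msgs, "recordsTotal must equal the sum of area record counts")
    }
    if (sum(a$n_records[a$flagged]) != object@recordsSuppressed) {
      msgs <- c(msgs, "recordsSuppressed must equal records in flagged areas")
    }
  }
  if (length(msgs)) msgs else TRUE
})
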