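#' Accessors for sdcArea classes
#'
#' Small accessor generics so user code never reaches into slots:
#' `qidVariables()` returns a scheme's variable table, `ethnicityVariants()`
#' its ethnicity-variant names; `riskCoef()` a model's coefficient vector and
#' `thresholdLabel()` its threshold; `popTable()`, `populationRecords()` and
#' `sampleRecords()` the components of a synthetic population;
#' `classSpectrum()` the frequency-of-frequencies vector of an
#' [EquivalenceSpectrum].
#'
#' @param x an sdcArea object.
#' @return The accessed component; see the class documentation.
#' @name accessors
#' @examples
#' sch <- defaultQidScheme()
#' head(qidVariables(sch))
#' ethnicityVariants(sch)
NULL

#' @rdname accessors
#' @export
setGeneric("qidVariables", function(x) standardGeneric("qidVariables"))

#' @rdname accessors
#' @export
setGeneric("ethnicityVariants", function(x) standardGeneric("ethnicityVariants"))

#' @rdname accessors
#' @export
setGeneric("riskCoef", function(x) standardGeneric("riskCoef"))

#' @rdname accessors
#' @export
setGeneric("thresholdLabel", function(x) standardGeneric("thresholdLabel"))

#' @rdname accessors
#' @export
setGeneric("popTable", function(x) standardGeneric("popTable"))

#' @rdname accessors
#' @export
setGeneric("populationRecords", function(x) standardGeneric("populationRecords"))

#' @rdname accessors
#' @export
setGeneric("sampleRecords", function(x) standardGeneric("sampleRecords"))

#' @rdname accessors
#' @export
setGeneric("classSpectrum", function(x) standardGeneric("classSpectrum"))

#' @rdname accessors
setMethod("qidVariables", "QidScheme", function(x) x@variables)

#' @rdname accessors
setMethod("ethnicityVariants", "QidScheme", function(x) x@ethnicityVariants)

#' @rdname accessors
setMethod("riskCoef", "LogitRiskModel", function(x) x@coef)

#' @rdname accessors
setMethod("thresholdLabel", "LogitRiskModel", function(x) x@thresholdLabel)

#' @rdname accessors
setMethod("thresholdLabel", "SuppressionReport", function(x) x@thresholdLabel)

#' @rdname accessors
setMethod("popTable", "SyntheticPopulation", function(x) x@popTable)

#' @rdname accessors
setMethod("populationRecords", "SyntheticPopulation", function(x) x@population)

#' @rdname accessors
setMethod("sampleRecords", "SyntheticPopulation", function(x) x@sample)

#' @rdname accessors
setMethod("classSpectrum", "EquivalenceSpectrum", function(x) x@f)

setMethod("show", "QidScheme", function(object) {
  v <- object@variables
  cat("QidScheme with", nrow(v), "quasi-identifiers\n")
  cat("  high utility:",
      paste(v$name[v$utility_class == "high_utility"], collapse = ", "), "\n")
  cat("  sensitive:   ",
      paste(v$name[v$utility_class == "sensitive"], collapse = ", "), "\n")
  cat("  ethnicity variants (generic '", object@genericName, "'): ",
      paste(object@ethnicityVariants, collapse = ", "), "\n", sep = "")
})

setMethod("show", "EquivalenceSpectrum", function(object) {
  cat("EquivalenceSpectrum:", object@nRecords, "records in",
      object@nClasses, "classes\n")
  if (length(object@f)) {
    cat("  f_j:", paste0("j=", names(object@f), ":", object@f, collapse = "  "),
        "\n")
  }
})

setMethod("show", "LogitRiskModel", function(object) {
  cat("LogitRiskModel (", object@provenance, ", ", object@thresholdLabel,
      " threshold)\n", sep = "")
  print(round(object@coef, 4))
  cat("  centering: POP ", format(object@popCenter), ", MaxCombs ",
      format(object@maxcombsCenter), "; scale ", format(object@scale),
      "\n", sep = "")
  if (isTRUE(object@fitInfo$separation)) {
    cat("  warning: possible complete separation in the fit\n")
  }
})

setMethod("show", "SyntheticPopulation", function(object) {
  cat("SyntheticPopulation:", nrow(object@popTable), "areas,",
      nrow(object@population), "persons,",
      nrow(object@sample), "sampled (fraction",
      format(object@samplingFraction), ")\n")
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (pooled ", nrow(object@folds), "-fold CV)\n", sep = "")
  cat("  AUC        ", format(round(object@auc, 4)), "\n")
  cat("  sensitivity", format(round(object@sensitivity, 4)), "\n")
  cat("  specificity", format(round(object@specificity, 4)), "\n")
  cat("  confusion  tp=", object@confusion["tp"], " fp=",
      object@confusion["fp"], " tn=", object@confusion["tn"], " fn=",
      object@confusion["fn"], "\n", sep = "")
})

setMethod("show", "SuppressionReport", function(object) {
  cat("SuppressionReport (", object@thresholdLabel, " threshold)\n", sep = "")
  cat("  areas flagged:", sum(object@areas$flagged), "of",
      nrow(object@areas), "\n")
  cat("  records suppressed:", object@recordsSuppressed, "of",
      object@recordsTotal,
      sprintf("(%.1f%%)", object@percentSuppressed), "\n")
})
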