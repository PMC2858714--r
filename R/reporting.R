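validatePopTable <- function(popTable) {
  if (!all(c("area", "pop") %in% names(popTable))) {
    stop("population table needs columns 'area' and 'pop'")
  }
  dup <- duplicated(popTable$area)
  if (any(dup)) {
    stop("population table has duplicate area code(s): ",
         paste(unique(popTable$area[dup]), collapse = ", "))
  }
  if (any(!is.finite(popTable$pop)) || any(popTable$pop < 1)) {
    stop("population counts must be positive")
  }
  invisible(TRUE)
}

#' Read and write record and population tables
#'
#' CSV I/O for the tool's two tabular inputs. `readRecordTable()` reads a
#' person-level table and checks the area column has no missing codes;
#' `readPopulationTable()` reads an `area,pop` lookup and rejects duplicate
#' area codes. Malformed rows are reported with their line numbers.
#'
#' @param path CSV path.
#' @param areaCol name of the area column in the record table.
#' @return A data.frame.
#' @export
readRecordTable <- function(path, areaCol = "area") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = stats::setNames("character", areaCol))
  if (!areaCol %in% names(d)) {
    stop("record table has no '", areaCol, "' column")
  }
  bad <- which(is.na(d[[areaCol]]) | d[[areaCol]] == "")
  if (length(bad)) {
    stop("missing area code on data line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  d
}

#' @rdname readRecordTable
#' @export
readPopulationTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(area = "character"))
  validatePopTable(d)
  bad <- which(is.na(d$pop))
  if (length(bad)) {
    stop("missing population count on data line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  d
}

#' @rdname readRecordTable
#' @param x data.frame to write.
#' @export
writeRecordTable <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Suppression report for a dataset under a threshold model
#'
#' Applies a small-area decision rule to every area of a record table and
#' reports how many records would have to be suppressed (all records in
#' flagged areas are withheld). The rule is either a fitted/published
#' [LogitRiskModel] — each area is flagged when its predicted probability
#' of exceeding the model's uniqueness threshold is above the cutoff — or
#' the conservative 0% rule (`model = "zero"`), which flags any area whose
#' estimated population uniqueness on the given quasi-identifiers is above
#' zero.
#'
#' The MaxCombs value is computed once from the scheme and member list and
#' shared across areas; only the population size varies.
#'
#' @param records person-level data.frame with an area column.
#' @param popTable data.frame with columns `area`, `pop`; every area in
#'   `records` must have an entry (offenders are listed otherwise).
#' @param model a [LogitRiskModel], or `"zero"` for the 0% rule.
#' @param scheme a [QidScheme] declaring the quasi-identifiers.
#' @param members character vector of quasi-identifier names present in
#'   `records`.
#' @param samplingFraction fraction of the population the records represent
#'   (used by the 0% rule's uniqueness estimate; 1 for a complete dataset).
#' @param cutoff probability cutoff for model-based flagging.
#' @param areaCol name of the area column.
#' @return A [SuppressionReport].
#' @export
suppressionReport <- function(records, popTable, model, scheme, members,
                              samplingFraction = 1, cutoff = 0.5,
                              areaCol = "area") {
  validatePopTable(popTable)
  if (!areaCol %in% names(records)) {
    stop("record table has no '", areaCol, "' column")
  }
  counts <- table(as.character(records[[areaCol]]))
  areas <- names(counts)
  missing_pop <- setdiff(areas, as.character(popTable$area))
  if (length(missing_pop)) {
    stop("no population entry for area(s): ",
         paste(missing_pop, collapse = ", "))
  }
  pops <- popTable$pop[match(areas, as.character(popTable$area))]

  if (identical(model, "zero")) {
    est <- uniquenessEstimates(records, members, popTable, samplingFraction,
                               areaCol = areaCol)
    flagged <- est$est_population_uniqueness[match(areas, est$area)] > 0
    prob <- rep(NA_real_, length(areas))
    label <- "0%"
  } else {
    stopifnot(is(model, "LogitRiskModel"))
    M <- maxCombs(scheme, members)
    prob <- predictRisk(model, pops, rep(M, length(areas)))
    flagged <- prob > cutoff
    label <- model@thresholdLabel
  }

  areasDf <- data.frame(area = areas, n_records = as.integer(counts),
                        pop = pops, probability = prob, flagged = flagged,
                        stringsAsFactors = FALSE)
  total <- sum(areasDf$n_records)
  supp <- sum(areasDf$n_records[areasDf$flagged])
  new("SuppressionReport", thresholdLabel = label, areas = areasDf,
      recordsTotal = as.integer(total), recordsSuppressed = as.integer(supp),
      percentSuppressed = 100 * supp / total)
}

#' Write a suppression report as JSON
#'
#' Serialises a [SuppressionReport] to the JSON structure described by the
#' schema shipped at `inst/extdata/suppression-report-schema.json`.
#'
#' @param report a [SuppressionReport].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeSuppressionReport <- function(report, path) {
  stopifnot(is(report, "SuppressionReport"))
  obj <- list(
    threshold_label = report@thresholdLabel,
    records_total = report@recordsTotal,
    records_suppressed = report@recordsSuppressed,
    percent_suppressed = report@percentSuppressed,
    areas = report@areas
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Log a message to standard error with a level prefix
#'
#' Minimal leveled logging for the command-line workflow: a disclosure
#' control run should leave an auditable trace (seed, inputs, row counts).
#'
#' @param level one of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @param ... message parts, passed to `paste0`.
#' @param minLevel messages below this level are dropped.
#' @return Invisibly, the formatted message.
#' @export
sdcLog <- function(level = "INFO", ..., minLevel = "INFO") {
  levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)
  if (levels[[level]] < levels[[minLevel]]) return(invisible(NULL))
  msg <- paste0("[", level, "] ", format(Sys.time(), "%H:%M:%S"), " ",
                paste0(...))
  message(msg)
  invisible(msg)
}
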