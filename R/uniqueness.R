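#' Equivalence-class spectrum of an area
#'
#' Groups an area's records by their exact value combination on the model's
#' member variables and tabulates the class-size frequencies. Missing values
#' form their own category: a record with an unrecorded value is still
#' distinguishable from records carrying any observed value, so collapsing
#' it into an existing class would understate uniqueness.
#'
#' @param records data.frame of person-level records.
#' @param members character vector of quasi-identifier column names.
#' @param area optional area code; if supplied, records are filtered to
#'   `records[[areaCol]] == area` first.
#' @param areaCol name of the area-code column (default `"area"`).
#' @return An [EquivalenceSpectrum].
#' @examples
#' d <- data.frame(area = "X", a = c(1, 1, 1, 2, 2, 3), b = 1)
#' equivalenceSpectrum(d, c("a", "b"))  # f = {3:1, 2:1, 1:1}
#' @export
equivalenceSpectrum <- function(records, members, area = NULL,
                                areaCol = "area") {
  missing_cols <- setdiff(members, names(records))
  if (length(missing_cols)) {
    stop("model member(s) not present as columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.null(area)) {
    if (!areaCol %in% names(records)) {
      stop("area column '", areaCol, "' not found")
    }
    records <- records[records[[areaCol]] == area, , drop = FALSE]
    if (!nrow(records)) stop("area '", area, "' has no records")
  }
  if (!nrow(records)) {
    return(new("EquivalenceSpectrum", f = integer(0), nRecords = 0L,
               nClasses = 0L))
  }
  key <- do.call(paste, c(lapply(records[members], function(x) {
    x <- as.character(x)
    x[is.na(x)] <- "<NA>"
    x
  }), sep = "\r"))
  sizes <- tabulate(factor(key))
  f <- table(sizes)
  fvec <- as.integer(f)
  names(fvec) <- names(f)
  new("EquivalenceSpectrum", f = fvec, nRecords = nrow(records),
      nClasses = length(sizes))
}

#' Sample uniqueness
#'
#' The proportion of records that are unique in the sample: the number of
#' size-1 equivalence classes divided by the number of records.
#'
#' @param spectrum an [EquivalenceSpectrum].
#' @return Proportion in \[0, 1\].
#' @export
sampleUniqueness <- function(spectrum) {
  stopifnot(is(spectrum, "EquivalenceSpectrum"))
  if (spectrum@nRecords < 1L) {
    stop("sample uniqueness is undefined for an empty area")
  }
  f1 <- spectrum@f["1"]
  if (is.na(f1)) f1 <- 0L
  as.numeric(f1) / spectrum@nRecords
}

#' Zayatz estimator of population uniqueness
#'
#' Estimates the proportion of the *population* that is unique on the
#' quasi-identifiers from the *sample* class-size spectrum. The population
#' class-size distribution is estimated naively from the sample spectrum,
#' `P(F = j) = f_j / sum(f)`; the probability that a population class of
#' size j contributes exactly one sampled record under binomial subsampling
#' at fraction p is `j p (1-p)^(j-1)`; Bayes' rule then gives the probability
#' that a sample unique is a population unique,
#' `P(F = 1 | f = 1)`. The estimated number of population uniques is the
#' number of sample uniques times that probability, scaled to the population
#' by dividing by the per-class detection probability `P(f = 1 | F = 1) = p`,
#' and the returned proportion (after dividing by the population size) is
#' clipped to \[0, 1\].
#'
#' With `method = "hypergeometric"` the subsampling probability uses the
#' exact without-replacement form `j * choose(N-j, n-1) / choose(N, n)`;
#' at the area sizes this tool targets the binomial form is an adequate and
#' standard approximation.
#'
#' @param spectrum an [EquivalenceSpectrum] of the sample.
#' @param samplingFraction sampling fraction p in (0, 1].
#' @param populationSize population size N of the area (>= sample size).
#' @param method `"binomial"` (default) or `"hypergeometric"`.
#' @return Estimated population uniqueness, a proportion in \[0, 1\].
#' @examples
#' d <- data.frame(a = c(1, 1, 2, 3, 4))
#' sp <- equivalenceSpectrum(d, "a")
#' zayatzUniqueness(sp, samplingFraction = 0.2, populationSize = 25)
#' @export
zayatzUniqueness <- function(spectrum, samplingFraction, populationSize,
                             method = c("binomial", "hypergeometric")) {
  stopifnot(is(spectrum, "EquivalenceSpectrum"))
  method <- match.arg(method)
  p <- samplingFraction
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p > 1) {
    stop("samplingFraction must be in (0, 1]")
  }
  N <- populationSize
  if (N < spectrum@nRecords) {
    stop("populationSize is smaller than the number of sampled records")
  }
  f <- spectrum@f
  if (!length(f)) return(0)
  f1 <- f["1"]
  if (is.na(f1) || f1 == 0L) return(0)

  j <- as.numeric(names(f))
  pF <- as.numeric(f) / sum(f)                     # naive P(F = j)
  if (method == "binomial") {
    detect <- j * p * (1 - p)^(j - 1)              # P(f = 1 | F = j)
    p11 <- p
  } else {
    n <- spectrum@nRecords
    detect <- exp(log(j) + lchoose(N - j, n - 1) - lchoose(N, n))
    detect[N - j < n - 1] <- 0
    p11 <- exp(lchoose(N - 1, n - 1) - lchoose(N, n))  # = n / N
  }
  denom <- sum(pF * detect)
  if (denom <= 0) return(0)
  i1 <- which(j == 1)
  pUniqueGivenSampleUnique <- pF[i1] * detect[i1] / denom
  estUniques <- as.numeric(f1) * pUniqueGivenSampleUnique / p11
  min(1, max(0, estUniques / N))
}

#' Pigeonhole (Dirichlet drawer) small-area flag
#'
#' With N individuals distributed over at most k equivalence classes, some
#' class must contain at least `ceiling(N / k)` individuals; if `N <= k`
#' the area can contain a unique individual, which under the conservative
#' any-unique criterion marks the area as likely high risk.
#'
#' @param populationSize N (>= 1).
#' @param maxCombs k, the maximum number of equivalence classes (>= 1).
#' @return List with `flag` (`TRUE` iff `N <= k`) and `minMaxClassSize`
#'   (`ceiling(N / k)`).
#' @examples
#' pigeonholeFlag(15, 48)   # flagged
#' pigeonholeFlag(100, 10)  # not flagged, some class has >= 10 members
#' @export
pigeonholeFlag <- function(populationSize, maxCombs) {
  stopifnot(populationSize >= 1, maxCombs >= 1)
  list(flag = populationSize <= maxCombs,
       minMaxClassSize = ceiling(populationSize / maxCombs))
}

#' Expected non-unique fraction under uniform allocation
#'
#' If N individuals are assigned independently and uniformly to k classes,
#' the probability a given individual shares its class with at least one
#' other is `1 - (1 - 1/k)^(N-1)`; by linearity this is the expected
#' fraction of non-unique individuals. It quantifies how much the
#' pigeonhole criterion overstates risk: even in an area small enough to
#' guarantee a possible unique, a sizable fraction is expected to be
#' non-unique.
#'
#' @param populationSize N (>= 1).
#' @param maxCombs k (>= 1).
#' @return Expected non-unique proportion in \[0, 1\].
#' @examples
#' expectedNonuniqueUniform(15, 48)  # about 0.255, i.e. 26%
#' @export
expectedNonuniqueUniform <- function(populationSize, maxCombs) {
  stopifnot(populationSize >= 1, maxCombs >= 1)
  1 - (1 - 1 / maxCombs)^(populationSize - 1)
}

#' Threshold indicators for estimated uniqueness
#'
#' Binary indicators that estimated population uniqueness is strictly above
#' the 5% and 20% thresholds. Exactly 5% (or 20%) is not flagged.
#'
#' @param estimate estimated population uniqueness in \[0, 1\].
#' @return Named integer vector `c(I05 = , I20 = )`.
#' @examples
#' thresholdIndicators(0.143)  # I05 = 1, I20 = 0
#' thresholdIndicators(0.56)   # I05 = 1, I20 = 1
#' @export
thresholdIndicators <- function(estimate) {
  stopifnot(all(estimate >= 0), all(estimate <= 1))
  c(I05 = as.integer(estimate > 0.05), I20 = as.integer(estimate > 0.20))
}

#' Per-area uniqueness estimates for a quasi-identifier model
#'
#' Runs the full uniqueness pipeline for every area in a record table:
#' equivalence classes, sample uniqueness, Zayatz population-uniqueness
#' estimate, and the 5%/20% threshold indicators.
#'
#' @param records data.frame of sampled person-level records with an area
#'   column.
#' @param members quasi-identifier column names defining the model.
#' @param popTable data.frame with columns `area`, `pop` giving each area's
#'   population size.
#' @param samplingFraction the fraction of the population the records
#'   represent.
#' @param areaCol name of the area column (default `"area"`).
#' @param method subsampling model passed to [zayatzUniqueness()].
#' @return data.frame, one row per area: `area`, `n_sample`, `pop`,
#'   `sample_uniqueness`, `est_population_uniqueness`, `I05`, `I20`.
#' @export
uniquenessEstimates <- function(records, members, popTable,
                                samplingFraction, areaCol = "area",
                                method = "binomial") {
  if (!areaCol %in% names(records)) {
    stop("area column '", areaCol, "' not found")
  }
  validatePopTable(popTable)
  areas <- sort(unique(as.character(records[[areaCol]])))
  missing_pop <- setdiff(areas, as.character(popTable$area))
  if (length(missing_pop)) {
    stop("no population entry for area(s): ",
         paste(missing_pop, collapse = ", "))
  }
  res <- lapply(areas, function(a) {
    sp <- equivalenceSpectrum(records, members, area = a, areaCol = areaCol)
    N <- popTable$pop[match(a, as.character(popTable$area))]
    est <- zayatzUniqueness(sp, samplingFraction, max(N, sp@nRecords),
                            method = method)
    ind <- thresholdIndicators(est)
    data.frame(area = a, n_sample = sp@nRecords, pop = N,
               sample_uniqueness = sampleUniqueness(sp),
               est_population_uniqueness = est,
               I05 = ind[["I05"]], I20 = ind[["I20"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
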