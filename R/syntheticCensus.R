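#' Specification for a synthetic census-like population
#'
#' Describes the multi-area categorical population the generator produces:
#' number of areas, the range of area population sizes (drawn log-uniformly,
#' matching the right-skewed size distribution of real postal areas), the
#' quasi-identifier scheme, the per-variable category distribution, optional
#' latent-class dependence between variables, and the per-area sampling
#' fraction of the long-form-style sample.
#'
#' Category distributions:
#' * `list(type = "zipf", s = 1.2)` — rank-frequency probabilities
#'   proportional to `rank^-s` (the default; real demographic categories are
#'   strongly skewed, a few common values and a long tail);
#' * `list(type = "uniform")` — equal probabilities;
#' * `list(type = "explicit", probs = list(varname = c(...), ...))` —
#'   per-variable probability vectors.
#'
#' Latent-class dependence (`latentClasses = list(k = , weights = )`) draws
#' each person's class, then permutes every variable's category
#' probabilities per class, inducing positive association between variables
#' without changing the marginal skew.
#'
#' @param nAreas number of areas to generate.
#' @param popRange numeric length-2, min and max area population (default
#'   `c(200, 78457)`).
#' @param scheme a [QidScheme] (default [defaultQidScheme()]).
#' @param dist category distribution specification (see above).
#' @param latentClasses `NULL` for independent variables, or
#'   `list(k = , weights = )`.
#' @param samplingFraction per-area sampling fraction (default 0.2).
#' @param seed integer seed.
#' @return A validated specification list of class `"PopulationSpec"`.
#' @seealso [generatePopulation()]
#' @export
populationSpec <- function(nAreas, popRange = c(200, 78457),
                           scheme = defaultQidScheme(),
                           dist = list(type = "zipf", s = 1.2),
                           latentClasses = NULL, samplingFraction = 0.2,
                           seed = 1L) {
  stopifnot(nAreas >= 1, length(popRange) == 2L, popRange[1] >= 1,
            popRange[2] >= popRange[1], is(scheme, "QidScheme"),
            samplingFraction > 0, samplingFraction <= 1)
  if (!dist$type %in% c("zipf", "uniform", "explicit")) {
    stop("dist$type must be 'zipf', 'uniform' or 'explicit'")
  }
  if (dist$type == "zipf" && (is.null(dist$s) || dist$s <= 0)) {
    stop("zipf distribution needs exponent s > 0")
  }
  if (dist$type == "explicit") {
    for (nm in names(dist$probs)) {
      pr <- dist$probs[[nm]]
      if (abs(sum(pr) - 1) > 1e-8 || any(pr < 0)) {
        stop("explicit probabilities for '", nm, "' must be non-negative ",
             "and sum to 1")
      }
    }
  }
  if (!is.null(latentClasses)) {
    stopifnot(latentClasses$k >= 2,
              length(latentClasses$weights) == latentClasses$k,
              abs(sum(latentClasses$weights) - 1) < 1e-8)
  }
  structure(list(nAreas = as.integer(nAreas), popRange = popRange,
                 scheme = scheme, dist = dist, latentClasses = latentClasses,
                 samplingFraction = samplingFraction,
                 seed = as.integer(seed)),
            class = "PopulationSpec")
}

categoryProbs <- function(spec, varName, nCat) {
  d <- spec$dist
  switch(d$type,
    uniform = rep(1 / nCat, nCat),
    zipf = {
      w <- seq_len(nCat)^(-d$s)
      w / sum(w)
    },
    explicit = {
      pr <- d$probs[[varName]]
      if (is.null(pr)) stop("no explicit probabilities for '", varName, "'")
      if (length(pr) != nCat) {
        stop("explicit probabilities for '", varName, "' must have length ",
             nCat)
      }
      pr
    })
}

areaSeed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Generate a synthetic population with its long-form-style sample
#'
#' Draws area sizes log-uniformly within the specified range, generates each
#' person's quasi-identifier values per the specification (independently
#' across variables, or via latent classes when dependence is requested),
#' and draws a per-area simple random sample without replacement at the
#' sampling fraction. Each area uses a seed derived from the spec seed and
#' the area index, so output is deterministic and per-area draws are stable
#' under changes to the number of areas.
#'
#' @param spec a [populationSpec()].
#' @return A [SyntheticPopulation].
#' @examples
#' sp <- populationSpec(nAreas = 3, popRange = c(50, 100), seed = 7)
#' pop <- generatePopulation(sp)
#' pop
#' @export
generatePopulation <- function(spec) {
  stopifnot(inherits(spec, "PopulationSpec"))
  scheme <- spec$scheme
  v <- scheme@variables
  set.seed(spec$seed)
  sizes <- round(exp(stats::runif(spec$nAreas, log(spec$popRange[1]),
                                  log(spec$popRange[2]))))
  sizes <- pmax(1L, as.integer(sizes))
  areas <- sprintf("A%03d", seq_len(spec$nAreas))

  probs <- lapply(seq_len(nrow(v)), function(i) {
    categoryProbs(spec, v$name[i], v$n_categories[i])
  })
  names(probs) <- v$name

  lc <- spec$latentClasses
  classProbs <- NULL
  if (!is.null(lc)) {
    # per-class permutations of each variable's category probabilities
    set.seed(areaSeed(spec$seed, 0L))
    classProbs <- lapply(seq_len(lc$k), function(cls) {
      lapply(probs, function(pr) pr[sample.int(length(pr))])
    })
  }

  popList <- vector("list", spec$nAreas)
  sampList <- vector("list", spec$nAreas)
  for (i in seq_len(spec$nAreas)) {
    set.seed(areaSeed(spec$seed, i))
    n <- sizes[i]
    df <- data.frame(area = rep(areas[i], n), stringsAsFactors = FALSE)
    if (is.null(lc)) {
      for (nm in v$name) {
        df[[nm]] <- sample.int(length(probs[[nm]]), n, replace = TRUE,
                               prob = probs[[nm]])
      }
    } else {
      cls <- sample.int(lc$k, n, replace = TRUE, prob = lc$weights)
      for (nm in v$name) {
        x <- integer(n)
        for (kk in seq_len(lc$k)) {
          sel <- cls == kk
          if (any(sel)) {
            pr <- classProbs[[kk]][[nm]]
            x[sel] <- sample.int(length(pr), sum(sel), replace = TRUE,
                                 prob = pr)
          }
        }
        df[[nm]] <- x
      }
    }
    popList[[i]] <- df
    nSamp <- max(1L, round(spec$samplingFraction * n))
    sampList[[i]] <- df[sort(sample.int(n, nSamp)), , drop = FALSE]
  }

  population <- do.call(rbind, popList)
  rownames(population) <- NULL
  smp <- do.call(rbind, sampList)
  rownames(smp) <- NULL
  new("SyntheticPopulation",
      population = population, sample = smp,
      popTable = data.frame(area = areas, pop = sizes,
                            stringsAsFactors = FALSE),
      samplingFraction = spec$samplingFraction,
      scheme = scheme, spec = unclass(spec))
}

#' Exact ground-truth population uniqueness
#'
#' Computes, by exact counting over the full generated population, the true
#' proportion of unique individuals per area for each quasi-identifier
#' model. This is the oracle every uniqueness estimator is measured against.
#'
#' @param synth a [SyntheticPopulation].
#' @param models data.frame as returned by [enumerateModels()], or a subset
#'   of its rows.
#' @return data.frame with columns `area`, `model_id`, `members`,
#'   `max_combs`, `true_uniqueness`.
#' @export
trueUniqueness <- function(synth, models) {
  stopifnot(is(synth, "SyntheticPopulation"))
  pop <- synth@population
  areas <- synth@popTable$area
  out <- vector("list", nrow(models) * length(areas))
  pos <- 0L
  for (m in seq_len(nrow(models))) {
    members <- modelMembers(models$members[m])
    for (a in areas) {
      sp <- equivalenceSpectrum(pop, members, area = a)
      pos <- pos + 1L
      out[[pos]] <- data.frame(
        area = a, model_id = models$model_id[m],
        members = models$members[m], max_combs = models$max_combs[m],
        true_uniqueness = sampleUniqueness(sp),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Build the risk-model observation table
#'
#' Produces one observation per (area x quasi-identifier model): the area's
#' population size (`pop`), the model's `max_combs`, and the 5%/20%
#' indicators derived either from the Zayatz estimate on the sample
#' (`mode = "estimate"`, mirroring what is observable in practice) or from
#' exact population counting (`mode = "oracle"`).
#'
#' @param synth a [SyntheticPopulation].
#' @param models data.frame of models (rows of [enumerateModels()] output).
#' @param mode `"estimate"` or `"oracle"`.
#' @param method subsampling model for [zayatzUniqueness()] in estimate
#'   mode.
#' @return data.frame with columns `area`, `model_id`, `pop`, `max_combs`,
#'   `uniqueness`, `I05`, `I20`.
#' @export
buildModelingTable <- function(synth, models, mode = c("estimate", "oracle"),
                               method = "binomial") {
  stopifnot(is(synth, "SyntheticPopulation"))
  mode <- match.arg(mode)
  src <- if (mode == "oracle") synth@population else synth@sample
  p <- if (mode == "oracle") 1 else synth@samplingFraction
  pt <- synth@popTable
  out <- vector("list", nrow(models))
  for (m in seq_len(nrow(models))) {
    members <- modelMembers(models$members[m])
    rows <- lapply(pt$area, function(a) {
      sp <- equivalenceSpectrum(src, members, area = a)
      N <- pt$pop[match(a, pt$area)]
      u <- if (mode == "oracle") sampleUniqueness(sp)
           else zayatzUniqueness(sp, p, max(N, sp@nRecords), method = method)
      ind <- thresholdIndicators(u)
      data.frame(area = a, model_id = models$model_id[m], pop = N,
                 max_combs = models$max_combs[m], uniqueness = u,
                 I05 = ind[["I05"]], I20 = ind[["I20"]],
                 stringsAsFactors = FALSE)
    })
    out[[m]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate risk observations from known logistic coefficients
#'
#' Draws (POP, MaxCombs) covariates in the regime the risk models target —
#' POP log-uniform over the area-size range, MaxCombs sampled from the
#' enumerated models' values — and labels each observation from a logistic
#' model with known coefficients on the centered/scaled predictors. Used to
#' measure parameter recovery of the unbalanced-data fitting methods
#' against a known truth.
#'
#' @param n number of observations.
#' @param coef named numeric `(intercept, pop, maxcombs, interaction)` on
#'   the centered/scaled predictor scale.
#' @param scaler list with `popCenter`, `maxcombsCenter`, and optionally
#'   `scale` (default 10,000), fixing the predictor transformation.
#' @param popRange area-size range for POP (default `c(200, 78457)`).
#' @param maxcombsValues pool of MaxCombs values to sample from (default:
#'   the 358 default-scheme model values).
#' @param seed integer seed.
#' @return List with `data` (data.frame `pop`, `max_combs`, `y`),
#'   `coef` (the true coefficients) and `scaler`.
#' @export
simulateRiskObservations <- function(n, coef, scaler,
                                     popRange = c(200, 78457),
                                     maxcombsValues = NULL, seed = 1L) {
  stopifnot(identical(names(coef), COEF_NAMES))
  if (is.null(scaler$scale)) scaler$scale <- 10000
  if (is.null(maxcombsValues)) {
    maxcombsValues <- enumerateModels(defaultQidScheme())$max_combs
  }
  set.seed(as.integer(seed))
  pop <- round(exp(stats::runif(n, log(popRange[1]), log(popRange[2]))))
  mc <- sample(maxcombsValues, n, replace = TRUE)
  cs <- centerScale(pop, mc, popCenter = scaler$popCenter,
                    maxcombsCenter = scaler$maxcombsCenter,
                    scale = scaler$scale)
  eta <- coef[["intercept"]] + coef[["pop"]] * cs$pop_cs +
    coef[["maxcombs"]] * cs$maxcombs_cs +
    coef[["interaction"]] * cs$pop_cs * cs$maxcombs_cs
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  list(data = data.frame(pop = pop, max_combs = mc, y = y),
       coef = coef, scaler = scaler)
}
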