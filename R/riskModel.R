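COEF_NAMES <- c("intercept", "pop", "maxcombs", "interaction")

#' Center and scale the risk-model predictors
#'
#' Both predictors are centered (to avoid collinearity with the interaction
#' term) and divided by a common scale, 10,000 by default (POP and MaxCombs
#' take large values and their product would otherwise overflow or dominate
#' the optimisation).
#'
#' @param pop population size(s), raw persons.
#' @param maxcombs MaxCombs value(s), raw combinations.
#' @param model a [LogitRiskModel] carrying the centering constants, or
#'   `NULL` if `popCenter`/`maxcombsCenter`/`scale` are given directly.
#' @param popCenter,maxcombsCenter,scale centering constants and scale used
#'   when `model` is `NULL`.
#' @return List with numeric vectors `pop_cs` and `maxcombs_cs`.
#' @examples
#' centerScale(20000, 576, popCenter = 10000, maxcombsCenter = 1000)
#' @export
centerScale <- function(pop, maxcombs, model = NULL, popCenter = NULL,
                        maxcombsCenter = NULL, scale = 10000) {
  if (!is.null(model)) {
    stopifnot(is(model, "LogitRiskModel"))
    popCenter <- model@popCenter
    maxcombsCenter <- model@maxcombsCenter
    scale <- model@scale
  }
  if (is.null(popCenter) || is.null(maxcombsCenter)) {
    stop("centering constants are required (supply a model or popCenter/",
         "maxcombsCenter)")
  }
  list(pop_cs = (pop - popCenter) / scale,
       maxcombs_cs = (maxcombs - maxcombsCenter) / scale)
}

riskLogit <- function(model, pop, maxcombs) {
  cs <- centerScale(pop, maxcombs, model = model)
  b <- model@coef
  b[["intercept"]] + b[["pop"]] * cs$pop_cs +
    b[["maxcombs"]] * cs$maxcombs_cs +
    b[["interaction"]] * cs$pop_cs * cs$maxcombs_cs
}

#' Predicted probability that an area is high risk
#'
#' Evaluates the logistic model
#' `logit(pi) = b0 + b1*POP_cs + b2*MaxCombs_cs + b3*POP_cs*MaxCombs_cs`
#' at the observation's centered/scaled predictors. `pi` is the probability
#' that the area's population uniqueness exceeds the model's threshold.
#'
#' @param model a [LogitRiskModel].
#' @param pop raw population size(s).
#' @param maxcombs raw MaxCombs value(s).
#' @return Probability vector (computed via `plogis`, stable for extreme
#'   logits).
#' @seealso [flagSmallArea()]
#' @export
predictRisk <- function(model, pop, maxcombs) {
  stopifnot(is(model, "LogitRiskModel"))
  stats::plogis(riskLogit(model, pop, maxcombs))
}

#' Flag an area as too small (high risk)
#'
#' An area is flagged when its predicted probability of exceeding the
#' model's uniqueness threshold is strictly greater than the cutoff. At the
#' default cutoff 0.5 this is equivalent to the model's logit being positive.
#'
#' @inheritParams predictRisk
#' @param cutoff probability cutoff in (0, 1); default 0.5.
#' @return Logical vector.
#' @export
flagSmallArea <- function(model, pop, maxcombs, cutoff = 0.5) {
  stopifnot(cutoff > 0, cutoff < 1)
  predictRisk(model, pop, maxcombs) > cutoff
}

#' Published threshold models
#'
#' Constructs the shipped decision rules for the 5% and 20% uniqueness
#' thresholds from their published down-sampling coefficients:
#' 5% model `(779.1, -37.35, 137.8, -6.5)` and 20% model
#' `(63.3, -6, 11.8, -1)` for (intercept, POP, MaxCombs, interaction) on
#' centered predictors scaled by 10,000.
#'
#' The centering constants used when these coefficients were estimated were
#' never disclosed, so they must be supplied by the caller; applying the
#' published coefficients with centering constants from a different
#' population than the one they were fitted on changes what the rule flags,
#' which is why this function refuses to guess them.
#'
#' @param threshold `"5%"` or `"20%"`.
#' @param popCenter,maxcombsCenter centering constants on the raw scale
#'   (required; no default exists).
#' @param scale predictor scale (default 10,000, as published).
#' @return A [LogitRiskModel] with `provenance = "published"`.
#' @examples
#' m <- publishedRiskModel("5%", popCenter = 10000, maxcombsCenter = 5000)
#' predictRisk(m, pop = 10000, maxcombs = 5000)  # ~1 at the centering point
#' @export
publishedRiskModel <- function(threshold = c("5%", "20%"), popCenter,
                               maxcombsCenter, scale = 10000) {
  threshold <- match.arg(threshold)
  if (missing(popCenter) || missing(maxcombsCenter)) {
    stop("publishedRiskModel(): the centering constants of the published ",
         "fits were not disclosed and must be supplied explicitly via ",
         "popCenter and maxcombsCenter; predictions are only meaningful ",
         "with centering appropriate for your data.")
  }
  b <- switch(threshold,
    "5%" = c(intercept = 779.1, pop = -37.35, maxcombs = 137.8,
             interaction = -6.5),
    "20%" = c(intercept = 63.3, pop = -6, maxcombs = 11.8, interaction = -1)
  )
  vc <- matrix(NA_real_, 4, 4, dimnames = list(COEF_NAMES, COEF_NAMES))
  new("LogitRiskModel", thresholdLabel = threshold, coef = b,
      popCenter = popCenter, maxcombsCenter = maxcombsCenter, scale = scale,
      provenance = "published", vcov = vc,
      fitInfo = list(method = "published", separation = FALSE))
}

checkRiskData <- function(data, response) {
  needed <- c("pop", "max_combs", response)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("risk data is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  y <- data[[response]]
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2L) {
    stop("both classes must be present in '", response, "'")
  }
  invisible(TRUE)
}

designMatrix <- function(data, popCenter, maxcombsCenter, scale) {
  cs <- centerScale(data$pop, data$max_combs, popCenter = popCenter,
                    maxcombsCenter = maxcombsCenter, scale = scale)
  cbind(intercept = 1, pop = cs$pop_cs, maxcombs = cs$maxcombs_cs,
        interaction = cs$pop_cs * cs$maxcombs_cs)
}

fitGlm <- function(X, y) {
  # extreme logits (hence probabilities numerically 0/1) are expected in
  # this regime and are not by themselves evidence of separation, so that
  # warning is muffled; separation is flagged on non-convergence, runaway
  # coefficients or a degenerate information matrix
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- fit$coefficients
  eta <- drop(X %*% co)
  pi_hat <- stats::plogis(eta)
  w <- pmax(pi_hat * (1 - pi_hat), 1e-12)
  XtWX <- crossprod(X * sqrt(w))
  degenerate <- FALSE
  vc <- tryCatch(solve(XtWX), error = function(e) {
    degenerate <<- TRUE
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(coef = co, vcov = vc, pi = pi_hat, w = w, XtWX = XtWX,
       separation = degenerate || !fit$converged || any(abs(co) > 1e4))
}

#' Fit a small-area risk model on unbalanced data
#'
#' Fits the logistic risk model `I ~ POP_cs * MaxCombs_cs` by maximum
#' likelihood with one of three treatments of class imbalance:
#'
#' * `"downsample"` — keeps all minority-class rows and an equal-size
#'   seeded simple random subsample of the majority class, fits on the
#'   balanced set, then applies the prior correction to the intercept:
#'   subtract `log(((1 - tau) / tau) * (ybar / (1 - ybar)))`, where `tau`
#'   is the full-data prevalence and `ybar` the balanced-sample prevalence.
#' * `"kz"` — the King–Zeng rare-events correction: ML fit on the full
#'   data, then subtraction of the small-sample bias term
#'   `(X'WX)^{-1} X'W xi` with `W = diag(pi(1-pi))`,
#'   `Q = X (X'WX)^{-1} X'` and `xi_i = 0.5 * Q_ii * (2 pi_i - 1)`.
#' * `"ml"` — plain maximum likelihood (for comparison).
#'
#' Centering constants are computed from the full training data (means of
#' POP and MaxCombs) unless a `scaler` overrides them, and are stored in the
#' returned model so prediction reuses them exactly.
#'
#' @param data data.frame with columns `pop`, `max_combs` and the binary
#'   response columns.
#' @param response `"I05"` or `"I20"` (any binary 0/1 column name works).
#' @param method `"downsample"`, `"kz"` or `"ml"`.
#' @param seed integer seed controlling the down-sampling draw.
#' @param scale predictor scale (default 10,000).
#' @param scaler optional list with `popCenter`, `maxcombsCenter` (and
#'   optionally `scale`) fixing the centering instead of data means.
#' @return A [LogitRiskModel]. If the fit shows signs of complete
#'   separation, a warning is raised and `fitInfo(separation)` is `TRUE`;
#'   coefficients are still returned.
#' @seealso [predictRisk()], [crossValidate()], [removeInfluential()]
#' @export
fitRiskModel <- function(data, response = c("I05", "I20"),
                         method = c("downsample", "kz", "ml"),
                         seed = 1L, scale = 10000, scaler = NULL) {
  response <- if (is.character(response) && length(response) == 1L &&
                  !response %in% c("I05", "I20")) response
              else match.arg(response)
  method <- match.arg(method)
  checkRiskData(data, response)
  y <- as.numeric(data[[response]])
  tau <- mean(y)

  if (!is.null(scaler)) {
    popCenter <- scaler$popCenter
    maxcombsCenter <- scaler$maxcombsCenter
    if (!is.null(scaler$scale)) scale <- scaler$scale
  } else {
    popCenter <- mean(data$pop)
    maxcombsCenter <- mean(data$max_combs)
  }

  if (method == "downsample") {
    minority <- if (tau <= 0.5) 1 else 0
    idx_min <- which(y == minority)
    idx_maj <- which(y != minority)
    set.seed(as.integer(seed))
    idx_maj <- sample(idx_maj, length(idx_min))
    idx <- c(idx_min, idx_maj)
    Xb <- designMatrix(data[idx, , drop = FALSE], popCenter, maxcombsCenter,
                       scale)
    yb <- y[idx]
    fit <- fitGlm(Xb, yb)
    ybar <- mean(yb)
    correction <- log(((1 - tau) / tau) * (ybar / (1 - ybar)))
    fit$coef["intercept"] <- fit$coef["intercept"] - correction
    info <- list(method = method, seed = as.integer(seed), prevalence = tau,
                 balanced_prevalence = ybar,
                 intercept_correction = -correction,
                 n = length(y), n_balanced = length(yb),
                 separation = fit$separation)
  } else {
    X <- designMatrix(data, popCenter, maxcombsCenter, scale)
    fit <- fitGlm(X, y)
    if (method == "kz") {
      fit$coef <- fit$coef - kzBiasTerm(X, fit$pi, fit$XtWX)
    }
    info <- list(method = method, seed = as.integer(seed), prevalence = tau,
                 n = length(y), separation = fit$separation)
  }

  if (fit$separation) {
    warning("possible complete separation or non-convergence; ",
            "coefficients returned but flagged in fitInfo")
  }
  co <- fit$coef
  names(co) <- COEF_NAMES
  new("LogitRiskModel",
      thresholdLabel = if (identical(response, "I20")) "20%" else "5%",
      coef = co, popCenter = popCenter, maxcombsCenter = maxcombsCenter,
      scale = scale, provenance = "fitted", vcov = fit$vcov, fitInfo = info)
}

#' King-Zeng small-sample bias term for a logistic fit
#'
#' Computes `(X'WX)^{-1} X'W xi` with `W = diag(pi(1-pi))`,
#' `Q = X (X'WX)^{-1} X'` and `xi_i = 0.5 * Q_ii * (2 pi_i - 1)`, the bias
#' of the ML logit estimator that the rare-events correction subtracts.
#' Exposed so the correction can be verified against direct matrix
#' arithmetic.
#'
#' @param X design matrix (including the intercept column).
#' @param pi fitted probabilities of the ML fit.
#' @param XtWX optional precomputed `X'WX`.
#' @return Numeric bias vector, one entry per coefficient.
#' @export
kzBiasTerm <- function(X, pi, XtWX = NULL) {
  w <- pi * (1 - pi)
  if (is.null(XtWX)) XtWX <- crossprod(X * sqrt(w))
  XtWXinv <- solve(XtWX)
  # Q_ii = x_i' (X'WX)^{-1} x_i, computed row-wise
  Qii <- rowSums((X %*% XtWXinv) * X)
  xi <- 0.5 * Qii * (2 * pi - 1)
  drop(XtWXinv %*% crossprod(X, w * xi))
}

#' Wald confidence intervals for a fitted risk model
#'
#' @param model a fitted [LogitRiskModel].
#' @param level confidence level (default 0.95).
#' @return data.frame with columns `coef`, `estimate`, `lower`, `upper`.
#' @export
riskModelConfint <- function(model, level = 0.95) {
  stopifnot(is(model, "LogitRiskModel"))
  se <- sqrt(diag(model@vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(coef = COEF_NAMES, estimate = unname(model@coef),
             lower = unname(model@coef - z * se),
             upper = unname(model@coef + z * se),
             stringsAsFactors = FALSE)
}

#' Remove influential observations before fitting
#'
#' Fits a preliminary maximum-likelihood logit, computes standardized
#' leave-one-out coefficient changes (dfbetas), and removes, in a single
#' pass, every observation whose largest absolute dfbeta exceeds the cutoff
#' (default `2 / sqrt(n)`). Aborts if removal would leave a response class
#' empty.
#'
#' @inheritParams fitRiskModel
#' @param cutoff dfbetas cutoff; `Inf` removes nothing.
#' @return List with `kept` (the filtered data.frame), `removedFraction`,
#'   and `removed` (row indices of the dropped observations).
#' @export
removeInfluential <- function(data, response = c("I05", "I20"),
                              cutoff = NULL, scale = 10000) {
  response <- if (is.character(response) && length(response) == 1L &&
                  !response %in% c("I05", "I20")) response
              else match.arg(response)
  checkRiskData(data, response)
  n <- nrow(data)
  if (is.null(cutoff)) cutoff <- 2 / sqrt(n)
  y <- as.numeric(data[[response]])
  X <- designMatrix(data, mean(data$pop), mean(data$max_combs), scale)
  df <- as.data.frame(X[, -1, drop = FALSE])
  df$.y <- y
  g <- withCallingHandlers(
    stats::glm(.y ~ pop + maxcombs + interaction, data = df,
               family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  db <- stats::dfbetas(g)
  score <- apply(abs(db), 1L, max)
  removed <- which(score > cutoff)
  if (length(removed)) {
    yk <- y[-removed]
    if (length(unique(yk)) < 2L) {
      stop("influence-based removal would empty a response class; ",
           "raise the cutoff")
    }
    kept <- data[-removed, , drop = FALSE]
  } else {
    kept <- data
  }
  list(kept = kept, removedFraction = length(removed) / n, removed = removed)
}

#' Read / write a risk-model file
#'
#' Risk models serialise to a small YAML file carrying the threshold label,
#' coefficients, centering constants, scale, provenance and fit metadata.
#'
#' @param path file path.
#' @return `readRiskModel()` returns a [LogitRiskModel];
#'   `writeRiskModel()` invisibly returns `path`.
#' @export
readRiskModel <- function(path) {
  cfg <- yaml::read_yaml(path)
  co <- unlist(cfg$coefficients)[COEF_NAMES]
  vc <- matrix(NA_real_, 4, 4, dimnames = list(COEF_NAMES, COEF_NAMES))
  if (!is.null(cfg$vcov)) {
    vc <- matrix(unlist(cfg$vcov), 4, 4,
                 dimnames = list(COEF_NAMES, COEF_NAMES))
  }
  new("LogitRiskModel", thresholdLabel = cfg$threshold_label, coef = co,
      popCenter = cfg$scaler$pop_center,
      maxcombsCenter = cfg$scaler$maxcombs_center,
      scale = cfg$scaler$scale, provenance = cfg$provenance,
      vcov = vc, fitInfo = if (is.null(cfg$fit_info)) list() else cfg$fit_info)
}

#' @rdname readRiskModel
#' @param model a [LogitRiskModel] to serialise.
#' @export
writeRiskModel <- function(model, path) {
  stopifnot(is(model, "LogitRiskModel"))
  cfg <- list(
    threshold_label = model@thresholdLabel,
    coefficients = as.list(model@coef),
    scaler = list(pop_center = model@popCenter,
                  maxcombs_center = model@maxcombsCenter,
                  scale = model@scale),
    provenance = model@provenance,
    fit_info = model@fitInfo
  )
  if (all(is.finite(model@vcov))) cfg$vcov <- as.numeric(model@vcov)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
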