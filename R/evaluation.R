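#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation with midrank tie handling: the
#' probability that a randomly chosen positive (high-risk) observation
#' receives a higher score than a randomly chosen negative one, with ties
#' counted half.
#'
#' @param scores numeric scores (e.g. predicted probabilities).
#' @param labels binary labels, 1 = high risk.
#' @return AUC in \[0, 1\].
#' @examples
#' aucScore(c(0.9, 0.1), c(1, 0))  # 1
#' aucScore(c(0.5, 0.5), c(1, 0))  # 0.5
#' @export
aucScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC is undefined with only one class present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion matrix for flagged vs actual high risk
#'
#' @param flagged logical or 0/1 predictions (1 = predicted high risk).
#' @param labels binary actual labels (1 = actually above the threshold).
#' @return Named integer vector `(tp, fp, tn, fn)`.
#' @export
confusionCounts <- function(flagged, labels) {
  flagged <- as.logical(flagged)
  labels <- as.numeric(labels)
  c(tp = sum(flagged & labels == 1),
    fp = sum(flagged & labels == 0),
    tn = sum(!flagged & labels == 0),
    fn = sum(!flagged & labels == 1))
}

#' Sensitivity and specificity of a confusion matrix
#'
#' Sensitivity is the proportion of actually high-risk observations
#' correctly flagged, `tp / (tp + fn)`; specificity the proportion of
#' actually low-risk observations correctly passed, `tn / (tn + fp)`.
#'
#' @param cm named vector with entries `tp`, `fp`, `tn`, `fn` (as returned
#'   by [confusionCounts()]).
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @examples
#' sensitivitySpecificity(c(tp = 87, fp = 4, tn = 996, fn = 13))
#' @export
sensitivitySpecificity <- function(cm) {
  cm <- cm[c("tp", "fp", "tn", "fn")]
  if (anyNA(cm)) stop("cm must carry tp, fp, tn, fn")
  if (cm[["tp"]] + cm[["fn"]] == 0 || cm[["tn"]] + cm[["fp"]] == 0) {
    stop("sensitivity/specificity undefined: a class has no observations")
  }
  c(sensitivity = cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]),
    specificity = cm[["tn"]] / (cm[["tn"]] + cm[["fp"]]))
}

stratifiedFolds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of a risk model
#'
#' Splits the observations into k folds stratified by the response (so rare
#' positives appear in every fold), fits the model on the k-1 training folds
#' with the requested unbalanced-data method — rebalancing/correction is
#' performed inside each training split only — and predicts the held-out
#' fold. Out-of-fold predictions are pooled into one confusion matrix at the
#' probability cutoff, and the AUC is computed on the pooled predicted
#' probabilities. With a fixed seed the whole run is reproducible.
#'
#' @inheritParams fitRiskModel
#' @param k number of folds (default 10).
#' @param cutoff probability cutoff for flagging (default 0.5).
#' @return An [EvalReport].
#' @export
crossValidate <- function(data, response = c("I05", "I20"),
                          method = c("downsample", "kz", "ml"), k = 10L,
                          seed = 1L, cutoff = 0.5, scale = 10000) {
  response <- if (is.character(response) && length(response) == 1L &&
                  !response %in% c("I05", "I20")) response
              else match.arg(response)
  method <- match.arg(method)
  checkRiskData(data, response)
  y <- as.numeric(data[[response]])
  if (min(table(y)) < k) {
    stop("need at least k rows in each class for stratified ", k,
         "-fold CV")
  }
  fold <- stratifiedFolds(y, k, seed)
  prob <- numeric(length(y))
  foldInfo <- vector("list", k)
  for (i in seq_len(k)) {
    test <- fold == i
    train <- data[!test, , drop = FALSE]
    m <- suppressWarnings(
      fitRiskModel(train, response = response, method = method,
                   seed = as.integer(seed) + i, scale = scale)
    )
    prob[test] <- predictRisk(m, data$pop[test], data$max_combs[test])
    foldInfo[[i]] <- data.frame(fold = i, n_test = sum(test),
                                n_pos_test = sum(y[test] == 1),
                                separation = isTRUE(m@fitInfo$separation))
  }
  cm <- confusionCounts(prob > cutoff, y)
  ss <- sensitivitySpecificity(cm)
  new("EvalReport",
      auc = aucScore(prob, y),
      sensitivity = ss[["sensitivity"]],
      specificity = ss[["specificity"]],
      confusion = stats::setNames(as.integer(cm), names(cm)),
      folds = do.call(rbind, foldInfo),
      seed = as.integer(seed))
}
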