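# Model module: the margin classifier on transferred components, stratified
# 10-fold cross-validation with pooled metrics, target labeling at a
# probability threshold, and the k-nearest-neighbor fallback for records
# that cannot go through the two-sample TCA mapping.

.CLASS_LEVELS <- c("neutral", "functional")   # factor order: 0, 1

#' Train the margin classifier
#'
#' Fits a support vector classifier with Platt-scaled probability outputs
#' on latent components (or any feature matrix).  Predictors are
#' standardized internally (the fitted center/scale travel with the model
#' and are re-applied at prediction), since latent components can differ in
#' scale by orders of magnitude and the RBF kernel uses one bandwidth for
#' all of them.  The bandwidth defaults to the median pairwise-distance
#' heuristic on the standardized predictors; pass `gamma` to override.
#' Deterministic for a fixed `seed`.
#'
#' @param x numeric matrix of predictors.
#' @param y 0/1 labels (1 = functional); both classes must be present.
#' @param cost soft-margin cost C (default 1).
#' @param gamma RBF kernel parameter; `NULL` uses `1/(2 s^2)` with `s` the
#'   median pairwise distance of `x`.
#' @param kernel SVM kernel, `"radial"` (default) or `"linear"`.
#' @param seed RNG seed for the internal probability calibration.
#' @return an `e1071::svm` fit with probability model.
#' @export
trainClassifier <- function(x, y, cost = 1, gamma = NULL,
                            kernel = c("radial", "linear"),
                            seed = 20211126L) {
  kernel <- match.arg(kernel)
  x <- .assertMatrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    .stopf("training labels contain a single class")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  xs <- sweep(sweep(x, 2L, ctr, "-"), 2L, scl, "/")
  if (is.null(gamma)) {
    s <- .medianHeuristic(xs)
    gamma <- 1 / (2 * s^2)
  }
  yf <- factor(.CLASS_LEVELS[y + 1L], levels = .CLASS_LEVELS)
  fit <- .withSeed(seed,
    e1071::svm(xs, yf, kernel = kernel, cost = cost, gamma = gamma,
               probability = TRUE, scale = FALSE))
  attr(fit, "prescale") <- list(center = ctr, scale = scl)
  fit
}

#' Functional probabilities from a trained classifier
#'
#' @param model fit from [trainClassifier()].
#' @param x matrix with the training predictor dimension.
#' @return numeric vector of P(functional) per row.
#' @export
predictProbability <- function(model, x) {
  x <- .assertMatrix(x)
  ps <- attr(model, "prescale")
  if (!is.null(ps))
    x <- sweep(sweep(x, 2L, ps$center, "-"), 2L, ps$scale, "/")
  p <- attr(stats::predict(model, x, probability = TRUE), "probabilities")
  unname(p[, "functional"])
}

# ---- metrics -------------------------------------------------------------

#' Binary confusion-matrix metrics
#'
#' Precision, recall, accuracy and Matthews correlation coefficient from
#' 0/1 truth and prediction vectors.  Degenerate denominators (no
#' predicted positives, no true positives, or an MCC denominator of zero)
#' yield 0.
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return named list with `precision`, `recall`, `accuracy`, `mcc`.
#' @export
confusionMetrics <- function(truth, predicted) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted))
    .stopf("'truth' and 'predicted' lengths differ")
  .confusionMetrics(truth, predicted)
}

.confusionMetrics <- function(truth, predicted) {
  tp <- sum(truth == 1L & predicted == 1L)
  tn <- sum(truth == 0L & predicted == 0L)
  fp <- sum(truth == 0L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  accuracy <- (tp + tn) / length(truth)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(precision = precision, recall = recall, accuracy = accuracy,
       mcc = mcc)
}

#' Rank-statistic AUC
#'
#' Mann-Whitney estimate of the area under the ROC curve: the probability
#' that a functional record outranks a neutral one, with ties counted 1/2
#' (midranks).  Invariant under strictly monotone transforms of the scores.
#'
#' @param truth 0/1 labels.
#' @param score real-valued scores, larger meaning more functional.
#' @return AUC in [0,1].
#' @export
rankAUC <- function(truth, score) {
  truth <- as.integer(truth)
  nPos <- sum(truth == 1L); nNeg <- sum(truth == 0L)
  if (nPos == 0L || nNeg == 0L)
    .stopf("AUC needs both classes present")
  r <- rank(score, ties.method = "average")
  (sum(r[truth == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

.stratifiedFolds <- function(y, nFolds, seed) {
  counts <- table(y)
  if (any(counts < nFolds))
    .stopf("class with %d record(s) cannot fill %d stratified folds",
           min(counts), nFolds)
  folds <- integer(length(y))
  .withSeed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the margin classifier
#'
#' Assigns stratified folds, trains on each complement, pools the held-out
#' probability predictions, and reports precision, accuracy, Matthews
#' correlation coefficient, recall (at probability threshold 0.5) and the
#' rank-statistic AUC over the pooled scores.
#'
#' @inheritParams trainClassifier
#' @param nFolds number of folds (default 10).
#' @param threshold probability cut for the thresholded confusion metrics.
#' @param ... passed to [trainClassifier()] (`cost`, `gamma`, `kernel`).
#' @return an [EvaluationReport-class].
#' @export
crossValidate <- function(x, y, nFolds = 10L, seed = 20211126L,
                          threshold = 0.5, ...) {
  x <- .assertMatrix(x)
  y <- as.integer(y)
  if (nFolds < 2L) .stopf("'nFolds' must be >= 2")
  if (length(unique(y)) < 2L) .stopf("both classes must be present")
  folds <- .stratifiedFolds(y, nFolds, seed)
  prob <- numeric(length(y))
  for (f in seq_len(nFolds)) {
    train <- folds != f
    fit <- trainClassifier(x[train, , drop = FALSE], y[train],
                           seed = seed + f, ...)
    prob[!train] <- predictProbability(fit, x[!train, , drop = FALSE])
  }
  cm <- .confusionMetrics(y, as.integer(prob >= threshold))
  new("EvaluationReport", precision = cm$precision, accuracy = cm$accuracy,
      mcc = cm$mcc, recall = cm$recall, auc = rankAUC(y, prob),
      nFolds = as.integer(nFolds), folds = folds, seed = as.integer(seed))
}

# ---- prediction ----------------------------------------------------------

.predictionFrame <- function(ids, prob, threshold, route) {
  data.frame(record_id = ids, probability = prob,
             label = ifelse(prob >= threshold, "functional", "neutral"),
             threshold = threshold, route = route,
             stringsAsFactors = FALSE)
}

#' Label target records with a trained classifier
#'
#' @param model fit from [trainClassifier()].
#' @param components matrix of target latent components (rows named by
#'   record id where available).
#' @param threshold probability at or above which a record is called
#'   functional (default 0.5).
#' @return data.frame with columns `record_id`, `probability`, `label`,
#'   `threshold`, `route` (= `"tca_svm"`).
#' @export
predictTarget <- function(model, components, threshold = 0.5) {
  components <- .assertMatrix(components)
  prob <- predictProbability(model, components)
  .predictionFrame(rownames(components) %||%
                     as.character(seq_len(nrow(components))),
                   prob, threshold, "tca_svm")
}

#' Nearest-neighbor prediction for novel microexons
#'
#' The two-sample TCA mapping needs a full dataset on each side, so a
#' single new record is scored against the reference catalog instead: its
#' probability is the mean stored probability of its `k` nearest references
#' by Euclidean distance in the standardized feature space (distance ties
#' broken by catalog order).
#'
#' @param catalog a [ReferenceCatalog-class].
#' @param query numeric matrix (or single vector) of raw-scale feature
#'   vectors.
#' @param k number of neighbors (default 5); must not exceed the catalog
#'   size.
#' @param threshold probability cut for the label (default 0.5).
#' @return data.frame as in [predictTarget()] with `route = "knn"`.
#' @export
knnPredict <- function(catalog, query, k = 5L, threshold = 0.5) {
  stopifnot(is(catalog, "ReferenceCatalog"))
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  query <- .assertMatrix(query)
  if (nrow(catalog@features) < k)
    .stopf("reference catalog has %d record(s), fewer than k = %d",
           nrow(catalog@features), k)
  refStd <- scaleFeatures(catalog@features, catalog@scaler)
  qStd <- scaleFeatures(query, catalog@scaler)
  d2 <- outer(rowSums(qStd^2), rowSums(refStd^2), "+") -
    2 * qStd %*% t(refStd)
  prob <- vapply(seq_len(nrow(qStd)), function(i) {
    nn <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
    mean(catalog@probabilities[nn])
  }, numeric(1))
  .predictionFrame(rownames(query) %||% as.character(seq_len(nrow(query))),
                   prob, threshold, "knn")
}

#' Count predictions at or above a probability threshold
#'
#' @param predictions a prediction data.frame (any object with a
#'   `probability` column) or a bare numeric vector of probabilities.
#' @param threshold probability cut.
#' @return integer count of records with `probability >= threshold`.
#' @examples
#' countAtThreshold(c(0.7, 0.4, 0.5), 0.5)  # 2
#' @export
countAtThreshold <- function(predictions, threshold) {
  prob <- if (is.numeric(predictions)) predictions else
    predictions$probability
  if (is.null(prob)) .stopf("no 'probability' column in predictions")
  sum(prob >= threshold)
}

#' Literature-reported functional microexon cases
#'
#' Nineteen microexons with published experimental evidence of function,
#' curated from the primary literature, together with the functional
#' probability each receives from the transfer model.  Coordinates are
#' 0-based starts on hg19 chromosomes; lengths are in nt.  Useful as a
#' positive-control panel: at threshold 0.5 the model calls 16 of the 19
#' functional.
#'
#' @return data.frame with columns `gene`, `chrom`, `start`, `length`,
#'   `probability`.
#' @export
literatureMicroexons <- function() {
  path <- system.file("extdata", "literature_microexons.tsv",
                      package = "microTCA", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
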