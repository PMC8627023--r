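test_that("confusion metrics match a loop-based oracle on random inputs", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    truth <- rbinom(n, 1, 0.5)
    pred <- rbinom(n, 1, 0.5)
    got <- confusionMetrics(truth, pred)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (truth[j] == 1 && pred[j] == 1) tp <- tp + 1
      if (truth[j] == 0 && pred[j] == 0) tn <- tn + 1
      if (truth[j] == 0 && pred[j] == 1) fp <- fp + 1
      if (truth[j] == 1 && pred[j] == 0) fn <- fn + 1
    }
    expect_equal(got$accuracy, (tp + tn) / n)
    if (tp + fp > 0) expect_equal(got$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(got$recall, tp / (tp + fn))
    den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    if (den > 0)
      expect_equal(got$mcc, (tp * tn - fp * fn) / den)
  }
})

test_that("calling everything functional on a balanced set is the textbook case", {
  truth <- rep(c(1, 0), 25)
  got <- confusionMetrics(truth, rep(1, 50))
  expect_equal(got$precision, 0.5)
  expect_equal(got$recall, 1)
  expect_equal(got$mcc, 0)
})

test_that("rank AUC matches pROC and survives monotone transforms", {
  skip_if_not_installed("pROC")
  set.seed(22)
  for (i in 1:10) {
    truth <- rbinom(60, 1, 0.5)
    if (length(unique(truth)) < 2) next
    score <- rnorm(60) + truth
    got <- rankAUC(truth, score)
    oracle <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                             direction = "<")))
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_equal(rankAUC(truth, plogis(3 * score - 1)), got)  # monotone map
    expect_equal(rankAUC(truth, exp(score)), got)
  }
})

test_that("AUC is near 1/2 under shuffled labels", {
  aucs <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(rnorm(400 * 4), 400)
    y <- rep(0:1, each = 200)[sample(400)]
    rep <- crossValidate(x, y, nFolds = 5, seed = s)
    rep@auc
  }, numeric(1))
  expect_lt(max(abs(aucs - 0.5)), 0.08)
})

test_that("cross-validation separates two distant Gaussian classes", {
  set.seed(23)
  x <- rbind(matrix(rnorm(100 * 4), 100), matrix(rnorm(100 * 4) + 6, 100))
  y <- rep(c(0L, 1L), each = 100)
  rep <- crossValidate(x, y, nFolds = 10, seed = 1)
  expect_gte(rep@accuracy, 0.98)
  expect_gte(rep@auc, 0.99)
  expect_identical(sort(unique(rep@folds)), 1:10)
  expect_identical(tabulate(rep@folds), rep(20L, 10))  # stratified balance
  # determinism: same data + seed reproduces the report
  rep2 <- crossValidate(x, y, nFolds = 10, seed = 1)
  expect_equal(as.data.frame(rep), as.data.frame(rep2))
  expect_error(crossValidate(x, rep(1L, 200)), "both classes")
  expect_error(crossValidate(x[1:12, ], y[c(1:10, 101:102)], nFolds = 10),
               "stratified")
})

test_that("the classifier is deterministic and separates its training set", {
  set.seed(24)
  x <- rbind(matrix(rnorm(60 * 3), 60), matrix(rnorm(60 * 3) + 5, 60))
  y <- rep(c(0L, 1L), each = 60)
  m1 <- trainClassifier(x, y, seed = 99)
  m2 <- trainClassifier(x, y, seed = 99)
  p1 <- predictProbability(m1, x); p2 <- predictProbability(m2, x)
  expect_identical(p1, p2)
  expect_gte(mean((p1 >= 0.5) == (y == 1)), 0.98)
  expect_error(trainClassifier(x, rep(1L, 120)), "single class")
})

test_that("target labeling thresholds probabilities with >= semantics", {
  set.seed(25)
  x <- rbind(matrix(rnorm(40 * 3), 40), matrix(rnorm(40 * 3) + 5, 40))
  y <- rep(c(0L, 1L), each = 40)
  fit <- trainClassifier(x, y, seed = 7)
  tgt <- matrix(rnorm(30 * 3) + 2.5, 30)
  pred0 <- predictTarget(fit, tgt, threshold = 0)
  expect_true(all(pred0$label == "functional"))     # every p >= 0
  pred2 <- predictTarget(fit, tgt, threshold = 1.01)
  expect_true(all(pred2$label == "neutral"))
  counts <- vapply(seq(0, 1, 0.1), function(th)
    countAtThreshold(predictTarget(fit, tgt, threshold = th), th),
    numeric(1))
  expect_false(is.unsorted(rev(counts)))            # monotone sweep
  expect_true(all(pred0$route == "tca_svm"))
})

test_that("KNN fallback equals a brute-force all-pairs scan", {
  set.seed(26)
  refX <- matrix(rnorm(200 * 25), 200,
                 dimnames = list(NULL, microFeatureNames()))
  refP <- runif(200)
  cat <- referenceCatalog(refX, refP)
  qry <- matrix(rnorm(20 * 25), 20)
  got <- knnPredict(cat, qry, k = 5)
  refStd <- scaleFeatures(refX, cat@scaler)
  qStd <- scaleFeatures(qry, cat@scaler)
  for (i in 1:20) {
    d <- apply(refStd, 1, function(r) sqrt(sum((qStd[i, ] - r)^2)))
    nn <- order(d)[1:5]
    expect_equal(got$probability[i], mean(refP[nn]))
  }
  expect_true(all(got$route == "knn"))
  expect_error(knnPredict(cat, qry, k = 300), "fewer than k")
})

test_that("an identity query with k = 1 returns its own stored probability", {
  set.seed(27)
  refX <- matrix(rnorm(50 * 25), 50,
                 dimnames = list(NULL, microFeatureNames()))
  refP <- runif(50)
  cat <- referenceCatalog(refX, refP)
  got <- knnPredict(cat, refX[17, , drop = FALSE], k = 1)
  expect_equal(got$probability, refP[17])
  # mean-of-neighbors arithmetic on a hand-built neighborhood
  near <- matrix(0, 5, 25); near[, 1] <- seq(0, 0.04, 0.01)
  far <- matrix(10, 45, 25) + matrix(rnorm(45 * 25), 45)
  cat2 <- referenceCatalog(rbind(near, far),
                           c(0.8, 0.7, 0.9, 0.6, 0.5, runif(45)))
  got2 <- knnPredict(cat2, rep(0, 25), k = 5)
  expect_equal(got2$probability, 0.70)
})

test_that("threshold counting reproduces the literature panel tallies", {
  lit <- literatureMicroexons()
  expect_identical(nrow(lit), 19L)
  expect_identical(countAtThreshold(lit, 0.5), 16L)
  expect_identical(countAtThreshold(lit, 0.6), 15L)
  expect_identical(countAtThreshold(numeric(0), 0.5), 0L)
  ths <- seq(0, 1, 0.05)
  counts <- vapply(ths, countAtThreshold, predictions = lit, numeric(1))
  expect_false(is.unsorted(rev(counts)))
})
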