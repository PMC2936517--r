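smallSample <- function(n = 30, L = 24, seed = 2) {
  set.seed(seed)
  mk <- function(seqs, ids, z) new("ProbeSet", id = ids, sequence = seqs,
                                   intensity = exp(z), normalized = z,
                                   designId = "toy")
  zp <- sort(runif(n, 1, 3), decreasing = TRUE)
  zn <- sort(runif(n, -3, -1))
  new("TrainingSample",
      positives = mk(randomDNA(n, L), sprintf("p%03d", 1:n), zp),
      negatives = mk(randomDNA(n, L), sprintf("n%03d", 1:n), zn),
      labels = c(zp, zn))
}

test_that("the SVR recovers a noiseless linear target within epsilon", {
  p <- diMismatchParams(5, 2, "single")
  set.seed(4)
  seqs <- randomDNA(40, 24)
  space <- buildFeatureSpace(seqs[1:10], p)
  wTrue <- rnorm(length(space), sd = 0.3)
  X <- featureMap(seqs, space)
  y <- as.numeric(X %*% wTrue) + 1.5

  mk <- function(i, ids) new("ProbeSet", id = ids, sequence = seqs[i],
                             intensity = exp(y[i]), normalized = y[i],
                             designId = "lin")
  ord <- order(-y)
  s <- new("TrainingSample", positives = mk(ord[1:20], sprintf("p%02d", 1:20)),
           negatives = mk(ord[21:40], sprintf("n%02d", 1:20)),
           labels = y[c(ord[1:20], ord[21:40])])
  cfg <- trainingConfig(epsilon = 0.1, cost = 1000, params = p)
  m <- trainRegressor(s, cfg, space = space)
  pred <- predictScores(m, seqs[c(ord[1:20], ord[21:40])])
  # within the epsilon tube up to the solver's own termination tolerance
  expect_lt(max(abs(pred - sampleLabels(s))), 0.1 + 1e-2)
})

test_that("primal weights reproduce the solver's own predictions", {
  s <- smallSample()
  p <- diMismatchParams(5, 2, "both")
  cfg <- trainingConfig(params = p, maxFeatures = 200)
  m <- trainRegressor(s, cfg)
  seqs <- c(probeSeqs(positives(s)), probeSeqs(negatives(s)))
  X <- featureMap(seqs, featureSpace(m))
  refit <- e1071::svm(x = X, y = sampleLabels(s), type = "eps-regression",
                      kernel = "linear", cost = 1, epsilon = 0.1,
                      scale = FALSE, fitted = FALSE)
  expect_equal(predictScores(m, seqs), as.numeric(predict(refit, X)),
               tolerance = 1e-6)
})

test_that("degenerate regression labels yield a constant model", {
  s <- smallSample()
  s@labels <- rep(1.5, length(s@labels))
  s@positives@normalized <- rep(1.5, 30)
  s@negatives@normalized <- rep(1.5, 30)
  cfg <- trainingConfig(params = diMismatchParams(5, 2), maxFeatures = 50)
  expect_warning(m <- trainRegressor(s, cfg), "degenerate")
  expect_equal(predictScores(m, randomDNA(5, 24)), rep(1.5, 5),
               tolerance = 0.1)
})

test_that("the SVM separates separable window sets and errors on one class", {
  p <- diMismatchParams(4, 0, "single")
  set.seed(8)
  pos <- vapply(randomDNA(15, 20), plantSite, "x", site = "AAAAAAAA")
  neg <- vapply(randomDNA(15, 20), plantSite, "x", site = "CCCCCCCC")
  w <- labeledWindowSet(c(pos, neg), rep(c(1, -1), each = 15))
  cfg <- trainingConfig(mode = "classification", params = p, maxFeatures = 50)
  m <- trainClassifier(w, cfg)
  s <- predictScores(m, windowSeqs(w))
  expect_identical(sign(s), as.numeric(windowLabels(w)))

  bad <- labeledWindowSet(pos, rep(1, 15))
  expect_error(trainClassifier(bad, cfg), "both classes")
})

test_that("detection of the top n behaves combinatorially", {
  x <- c(5, 4, 3, 2, 1)
  expect_identical(detectionTopN(x, x, 3), 3L)
  expect_identical(detectionTopN(rev(x), x, 2), 0L)
  expect_error(detectionTopN(x, x, 6), "exceeds")
  expect_error(detectionTopN(x, x[1:3], 2), "equal length")

  # permutation invariance through ids
  set.seed(9)
  pred <- rnorm(50); true <- rnorm(50); ids <- sprintf("i%02d", 1:50)
  d1 <- detectionTopN(pred, true, 10, ids)
  perm <- sample(50)
  d2 <- detectionTopN(pred[perm], true[perm], 10, ids[perm])
  expect_identical(d1, d2)

  # chance level matches the hypergeometric expectation n^2 / N
  set.seed(10)
  d <- vapply(1:400, function(i)
    detectionTopN(runif(500), runif(500), 25), integer(1))
  expect_lt(abs(mean(d) - 25^2 / 500), 0.4)
})

test_that("cross-validated AUC hits 1 for separable data and errors when unstratifiable", {
  p <- diMismatchParams(4, 0, "single")
  set.seed(12)
  pos <- vapply(randomDNA(30, 20), plantSite, "x", site = "AAAAAAAA")
  neg <- vapply(randomDNA(30, 20), plantSite, "x", site = "CCCCCCCC")
  w <- labeledWindowSet(c(pos, neg), rep(c(1, -1), each = 30))
  cfg <- trainingConfig(mode = "classification", params = p, maxFeatures = 50)
  cv <- crossvalAUC(w, cfg, folds = 5, seed = 1)
  expect_equal(cv$mean, 1)
  expect_length(cv$perFold, 5L)
  expect_error(crossvalAUC(w, cfg, folds = 40), "at least")
})

test_that("label-permuted windows cross-validate near chance", {
  p <- diMismatchParams(5, 1, "both")
  set.seed(20)
  aucs <- vapply(1:6, function(i) {
    seqs <- randomDNA(60, 24)
    w <- labeledWindowSet(seqs, sample(rep(c(1L, -1L), each = 30)))
    crossvalAUC(w, trainingConfig(mode = "classification", params = p,
                                  maxFeatures = 100),
                folds = 5, seed = i)$mean
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("models round-trip through JSON + TSV serialization", {
  s <- smallSample()
  cfg <- trainingConfig(params = diMismatchParams(5, 2), maxFeatures = 100)
  m <- trainRegressor(s, cfg)
  prefix <- tempfile()
  writeModel(m, prefix)
  back <- readModel(prefix)
  expect_identical(features(featureSpace(back)), features(featureSpace(m)))
  expect_equal(modelWeights(back), modelWeights(m))
  expect_equal(modelBias(back), modelBias(m))
  seqs <- randomDNA(5, 24)
  expect_equal(predictScores(back, seqs), predictScores(m, seqs))
})
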