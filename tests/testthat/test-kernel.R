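test_that("di-mismatch score reproduces the worked 13-mer examples", {
  pRaw <- diMismatchParams(13, 12, "single")   # threshold 0: raw counts
  p <- diMismatchParams(13, 5, "single")

  a <- "ACGTACGTACGTA"
  expect_identical(diMismatchScore(a, a, p), 12L)

  # four consecutive interior mismatches cost 5 mismatching dinucleotides
  b <- a
  substr(b, 5, 8) <- chartr("ACGT", "GTAC", substr(a, 5, 8))
  expect_identical(12L - diMismatchScore(a, b, pRaw), 5L)
  # 12 - 5 = 7 matching, exactly at the (13,5) threshold
  expect_identical(diMismatchScore(a, b, p), 7L)

  # four isolated mismatches at positions 1, 5, 9, 13 cost 6 of 12
  d <- a
  for (pos in c(1, 5, 9, 13))
    substr(d, pos, pos) <- chartr("ACGT", "GTAC", substr(a, pos, pos))
  expect_identical(12L - diMismatchScore(a, d, pRaw), 6L)
  # 6 matching dinucleotides fall below the threshold of 7
  expect_identical(diMismatchScore(a, d, p), 0L)
})

test_that("di-mismatch score handles small alphabetic cases and errors", {
  p <- diMismatchParams(4, 1, "single")
  expect_identical(diMismatchScore("ACGT", "ACGA", p), 2L)
  expect_identical(diMismatchScore("ACGT", "TTTT", p), 0L)
  expect_error(diMismatchScore("ACG", "ACGT", p), "ACG")
  expect_error(diMismatchScore("ACGT", "ACGN", p), "ACGN")

  # double-stranded mode takes the better strand
  pb <- diMismatchParams(4, 3, "both")
  expect_identical(diMismatchScore("ACGT", "TTTT", pb),
                   max(oracleDiScore("ACGT", "TTTT", 4, 3, both = TRUE), 0L))
  expect_identical(diMismatchScore("AAAA", "TTTT", pb), 3L)  # revcomp match
})

test_that("score is symmetric and monotone under added mismatches", {
  set.seed(101)
  pRaw <- diMismatchParams(13, 12, "single")
  for (i in 1:50) {
    a <- randomDNA(1, 13)
    b <- randomDNA(1, 13)
    expect_identical(diMismatchScore(a, b, pRaw), diMismatchScore(b, a, pRaw))
    expect_identical(diMismatchScore(a, b, pRaw),
                     as.integer(oracleRawMatches(a, b)))
  }
  # flipping one more position never increases the raw matching count
  for (i in 1:25) {
    a <- randomDNA(1, 13)
    b <- a
    prev <- 12L
    for (pos in sample(13)) {
      substr(b, pos, pos) <- chartr("ACGT", "CGTA", substr(b, pos, pos))
      cur <- diMismatchScore(a, b, pRaw)
      expect_lte(cur, prev)
      prev <- cur
    }
  }
})

test_that("consecutive interior mismatches beat any scattered interior placement", {
  a <- paste(rep("A", 13), collapse = "")
  pRaw <- diMismatchParams(13, 12, "single")
  flipAt <- function(pos) {
    b <- a
    for (p in pos) substr(b, p, p) <- "C"
    diMismatchScore(a, b, pRaw)
  }
  for (j in 2:4) {
    sets <- utils::combn(2:12, j, simplify = FALSE)   # interior positions only
    consec <- vapply(sets[vapply(sets, function(s)
      all(diff(s) == 1L), logical(1))], flipAt, integer(1))
    scattered <- vapply(sets[!vapply(sets, function(s)
      all(diff(s) == 1L), logical(1))], flipAt, integer(1))
    expect_true(min(consec) >= max(scattered))
    expect_identical(unique(consec), 12L - (j + 1L))
  }
})

test_that("feature spaces enumerate, canonicalize and order k-mers", {
  p13 <- diMismatchParams(13, 5, "single")
  s <- randomDNA(1, 36)
  fs <- buildFeatureSpace(s, p13)
  expect_lte(length(fs), 24L)
  expect_false(is.unsorted(features(fs)))

  p4 <- diMismatchParams(4, 1, "single")
  expect_identical(features(buildFeatureSpace("AAAAA", p4)), "AAAA")

  pb <- diMismatchParams(4, 1, "both")
  fs2 <- buildFeatureSpace(c("ACGT", oracleRevcomp("ACGT")), pb)
  expect_identical(features(fs2), "ACGT")   # self-complementary collapses
  # no feature is the reverse complement of another
  fs3 <- buildFeatureSpace(randomDNA(5, 20), pb)
  expect_false(any(oracleRevcomp(features(fs3)) < features(fs3)))

  expect_error(buildFeatureSpace("ACG", p13), "shorter")
  expect_error(buildFeatureSpace(character(0), p13))
})

test_that("feature map matches the brute-force oracle", {
  p <- diMismatchParams(5, 2, "single")
  set.seed(7)
  for (rep in 1:20) {
    seqs <- randomDNA(3, 20)
    space <- buildFeatureSpace(randomDNA(2, 20), p)
    got <- featureMap(seqs, space)
    want <- oracleFeatureMap(seqs, features(space), 5, 2, both = FALSE)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
  pb <- diMismatchParams(5, 2, "both")
  for (rep in 1:10) {
    seqs <- randomDNA(3, 20)
    space <- buildFeatureSpace(randomDNA(2, 20), pb)
    got <- featureMap(seqs, space)
    want <- oracleFeatureMap(seqs, features(space), 5, 2, both = TRUE)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("feature map handles self-feature, zero and ambiguous cases", {
  p <- diMismatchParams(6, 1, "single")
  f <- "ACGTAC"
  space <- buildFeatureSpace(c(f, "GGGGGG"), p)
  fm <- featureMap(f, space)
  expect_equal(unname(fm[1, f]), 5)          # d(f, f) = k - 1
  expect_equal(unname(fm[1, "GGGGGG"]), 0)   # below threshold

  # sequence with no window near any feature maps to zero
  expect_true(all(featureMap("TTTTTTTT", space) == 0))

  # windows containing N contribute nothing
  expect_true(all(featureMap("ACGNACGTAC", space) ==
                  featureMap("TTTTACGTAC", space)))
  expect_error(featureMap("ACG", space), "shorter")
})

test_that("kernel matrices are Gram matrices of the explicit vectors", {
  p <- diMismatchParams(5, 2, "both")
  set.seed(11)
  X <- randomDNA(10, 36)
  space <- buildFeatureSpace(X, p)
  K <- diKernelMatrix(X, space = space)
  expect_equal(K, t(K))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * sum(diag(K)))
  fm <- featureMap(X, space)
  expect_equal(K, tcrossprod(fm), tolerance = 1e-10)

  one <- diKernelMatrix(X[1], space = space)
  expect_equal(dim(one), c(1L, 1L))
  expect_equal(one[1, 1], sum(featureMap(X[1], space)^2))

  K2 <- diKernelMatrix(X[1:3], X[4:6], space = space)
  expect_equal(K2, tcrossprod(featureMap(X[1:3], space),
                              featureMap(X[4:6], space)))
})

test_that("k-mer contribution table reproduces explicit predictions", {
  p <- diMismatchParams(5, 2, "both")
  set.seed(13)
  space <- buildFeatureSpace(randomDNA(4, 30), p)
  w <- rnorm(length(space))
  model <- new("LinearSequenceModel", space = space, weights = w, bias = 0.3,
               config = trainingConfig(params = p, mode = "regression"))
  seq200 <- randomDNA(1, 200)
  fast <- predictScores(model, seq200)
  slow <- oraclePredict(seq200, features(space), w, 0.3, 5, 2, both = TRUE)
  expect_equal(fast, slow, tolerance = 1e-9)

  # single unit-weight feature tabulates to k - 1 at itself
  f <- features(space)[1]
  m1 <- new("LinearSequenceModel",
            space = new("FeatureSpace", features = f, params = p),
            weights = 1, bias = 0,
            config = trainingConfig(params = p, mode = "regression"))
  expect_equal(unname(kmerContributionTable(m1, f)), 4)

  # zero weights predict the bias everywhere
  m0 <- new("LinearSequenceModel", space = space,
            weights = numeric(length(space)), bias = 2.5,
            config = trainingConfig(params = p, mode = "regression"))
  expect_true(all(kmerContributionTable(m0) == 0))
  expect_equal(predictScores(m0, randomDNA(3, 40)), rep(2.5, 3))
})

test_that("feature spaces round-trip through their text format", {
  p <- diMismatchParams(7, 2, "both")
  space <- buildFeatureSpace(randomDNA(3, 25), p)
  path <- tempfile(fileext = ".txt")
  writeFeatureSpace(space, path)
  back <- readFeatureSpace(path)
  expect_identical(features(back), features(space))
  expect_identical(back@params@k, 7L)
  expect_identical(back@params@m, 2L)
  expect_identical(back@params@strandMode, "both")
})

test_that("parameter validity enforces the di-mismatch invariants", {
  p <- diMismatchParams(13, 5)
  expect_identical(minMatchingDinucs(p), 7L)
  expect_identical(kmerLength(p), 13L)
  expect_identical(maxMismatches(p), 5L)
  expect_error(diMismatchParams(1, 0), "k")
  expect_error(diMismatchParams(17, 5), "16")
  expect_error(diMismatchParams(5, 5), "m")
})
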