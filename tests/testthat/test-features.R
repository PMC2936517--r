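# a model whose features are noisy copies of two dissimilar consensus k-mers,
# embedded against sequences that contain one motif or the other
twoMotifEmbedding <- function(nPerGroup = 40, nSeq = 60, seed = 71) {
  set.seed(seed)
  consA <- "ATGCAAATGCCAT"
  consB <- "CCTAATTAGGTCA"
  mutate <- function(x, nmm) {
    for (pos in sample(13, nmm))
      substr(x, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(x, pos, pos)), 1)
    x
  }
  kmers <- c(consA, consB,
             vapply(1:nPerGroup, function(i) mutate(consA, sample(1:2, 1)), "x"),
             vapply(1:nPerGroup, function(i) mutate(consB, sample(1:2, 1)), "x"))
  rc <- oracleRevcomp(kmers)
  kmers <- unique(pmin(kmers, rc))   # strand-canonical form
  seqs <- randomDNA(nSeq, 36)
  half <- seq_len(nSeq / 2)
  seqs[half] <- vapply(seqs[half], plantSite, "x", site = consA)
  seqs[-half] <- vapply(seqs[-half], plantSite, "x", site = consB)
  p <- diMismatchParams(13, 5, "both")
  space <- new("FeatureSpace", features = sort(kmers), params = p)
  model <- new("LinearSequenceModel", space = space,
               weights = stats::runif(length(kmers), 0.1, 1), bias = 0,
               config = trainingConfig(params = p, mode = "regression"))
  list(model = model, seqs = seqs, consA = consA, consB = consB)
}

test_that("alignment vectors score exact hits at k and match a hand oracle", {
  p <- diMismatchParams(5, 2, "single")
  space <- new("FeatureSpace", features = sort(c("ACGTA", "GGGCC")),
               params = p)
  m <- new("LinearSequenceModel", space = space, weights = c(1, 1), bias = 0,
           config = trainingConfig(params = p, mode = "regression"))
  seqs <- c("TTACGTATT", "ACGGACCCA")
  emb <- alignmentScoreVectors(m, seqs)
  # exact occurrence scores k; otherwise the best ungapped forward overlap
  expect_identical(unname(emb@vectors["ACGTA", 1]), 5L)
  handBest <- max(vapply(1:5, function(o)
    sum(strsplit("ACGTA", "")[[1]] ==
        strsplit(substr(seqs[2], o, o + 4), "")[[1]]), integer(1)))
  expect_identical(unname(emb@vectors["ACGTA", 2]), handBest)
  # identical k-mers get identical vectors
  emb2 <- alignmentScoreVectors(m, seqs, kmers = c("ACGTA", "ACGTA"))
  expect_identical(unname(emb2@vectors[1, ]), unname(emb2@vectors[2, ]))
  expect_error(alignmentScoreVectors(m, character(0)), "empty")
})

test_that("two planted k-mer families are recovered by 2-means clustering", {
  e <- twoMotifEmbedding()
  emb <- alignmentScoreVectors(e$model, e$seqs)
  rep <- clusterModelFeatures(emb, topPerCluster = 500, seed = 1)
  al <- rbind(
    alignmentScoreVectors(e$model, e$consA)@vectors[, 1],
    alignmentScoreVectors(e$model, e$consB)@vectors[, 1])
  truth <- ifelse(al[1, ] > al[2, ], 1L, 2L)
  names(truth) <- emb@kmers
  clear <- names(truth)[abs(al[1, ] - al[2, ]) >= 2]
  expect_gte(randIndex(rep@assignment[clear], truth[clear]), 0.95)

  # seeded determinism: rerunning reproduces the assignment
  rep2 <- clusterModelFeatures(emb, topPerCluster = 500, seed = 1)
  expect_identical(rep@assignment, rep2@assignment)

  # fewer members than the cap: everything is kept and projected in 2D
  expect_identical(sort(rep@kept), sort(names(rep@assignment)))
  expect_identical(ncol(rep@projection), 2L)

  # degenerate embeddings are rejected
  flat <- emb
  flat@vectors <- matrix(3L, nrow = length(emb@kmers),
                         ncol = ncol(emb@vectors),
                         dimnames = dimnames(emb@vectors))
  expect_error(clusterModelFeatures(flat), "degenerate")
})

test_that("cluster representatives are top-quartile members nearest the centroid", {
  # hand-built: one cluster of 5 vectors, weights force the candidate set
  p <- diMismatchParams(5, 2, "single")
  kmers <- c("AAAAA", "AAAAC", "AAAAG", "CCCCC", "CCCCG")
  V <- rbind(c(10, 0), c(9, 1), c(8, 0), c(0, 10), c(1, 9))
  rownames(V) <- kmers
  emb <- new("FeatureEmbedding", kmers = kmers, vectors = V,
             weights = c(1, 5, 5, 2, 2), params = p)
  rep <- clusterModelFeatures(emb, topPerCluster = 5, seed = 4)
  reps <- selectClusterRepresentative(rep, emb)
  clA <- rep@assignment[["AAAAA"]]
  # top quartile of weights in cluster {1,5,5} excludes AAAAA; of the two
  # weight-5 members AAAAC is nearer the centroid (9, 1/3)
  expect_identical(unname(reps[clA]), "AAAAC")
  # representative is always a member of its own cluster
  for (cl in seq_along(reps))
    expect_identical(unname(rep@assignment[reps[cl]]), cl)
  # stability under positive weight rescaling
  emb2 <- emb; emb2@weights <- emb@weights * 7.5
  rep2 <- clusterModelFeatures(emb2, topPerCluster = 5, seed = 4)
  expect_identical(selectClusterRepresentative(rep2, emb2), reps)
})

test_that("embedding is invariant to positive-sequence permutation", {
  e <- twoMotifEmbedding(seed = 73)
  emb <- alignmentScoreVectors(e$model, e$seqs)
  perm <- sample(length(e$seqs))
  embP <- alignmentScoreVectors(e$model, e$seqs[perm])
  expect_identical(emb@vectors[, perm], embP@vectors)
  repA <- clusterModelFeatures(emb, seed = 2)
  repB <- clusterModelFeatures(embP, seed = 2)
  agree <- mean(repA@assignment == repB@assignment)
  expect_true(agree < 0.05 || agree > 0.95)   # up to label swap
})

test_that("expanding a feature recovers a consensus-dominated PSSM", {
  set.seed(75)
  kmer <- "ATGCAAATGCCAT"
  seqs <- vapply(randomDNA(60, 36), plantSite, "x", site = kmer)
  x <- expandFeatureToPSSM(kmer, seqs, topN = 50, pseudocount = 0.01)
  expect_identical(pssmWidth(x), 13L)
  expect_equal(rowSums(pssmMatrix(x)), rep(1, 13), tolerance = 1e-9)
  idx <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "T"))
  diag <- pssmMatrix(x)[cbind(1:13, idx)]
  expect_true(all(diag >= 50 / (50 + 4 * 0.01) - 1e-9))
  expect_error(expandFeatureToPSSM(kmer, seqs[1:10], topN = 50), "at least")
})

test_that("retraining on the full feature set reproduces the full model", {
  set.seed(77)
  mk <- function(seqs, ids, z) new("ProbeSet", id = ids, sequence = seqs,
                                   intensity = exp(z), normalized = z,
                                   designId = "t")
  zp <- sort(runif(20, 1, 3), decreasing = TRUE)
  zn <- sort(runif(20, -3, -1))
  s <- new("TrainingSample",
           positives = mk(randomDNA(20, 24), sprintf("p%02d", 1:20), zp),
           negatives = mk(randomDNA(20, 24), sprintf("n%02d", 1:20), zn),
           labels = c(zp, zn))
  cfg <- trainingConfig(params = diMismatchParams(5, 2), maxFeatures = 500)
  full <- trainRegressor(s, cfg)
  re <- retrainOnFeatureSubset(s, features(featureSpace(full)), cfg)
  probes <- randomDNA(10, 24)
  expect_equal(predictScores(re, probes), predictScores(full, probes),
               tolerance = 1e-6)
  expect_error(retrainOnFeatureSubset(s, character(0), cfg), "empty")
})

test_that("cluster reports serialize to TSV", {
  e <- twoMotifEmbedding(seed = 79)
  emb <- alignmentScoreVectors(e$model, e$seqs)
  rep <- clusterModelFeatures(emb, seed = 1)
  path <- tempfile(fileext = ".tsv")
  writeClusterReport(rep, path)
  tab <- utils::read.delim(path)
  expect_identical(nrow(tab), length(rep@kept))
  expect_true(all(c("kmer", "cluster", "weight", "x", "y") %in% names(tab)))
})
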