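makeProbes <- function(n, L = 36, seed = 1, designId = "toy") {
  set.seed(seed)
  probeSet(sprintf("p%04d", seq_len(n)), randomDNA(n, L),
           exp(rnorm(n)), designId = designId)
}

test_that("probe tables round-trip and reject malformed rows", {
  probes <- makeProbes(3)
  path <- tempfile(fileext = ".tsv")
  writeProbeTable(probes, path)
  back <- readProbeTable(path, designId = "toy")
  expect_identical(probeIds(back), probeIds(probes))
  expect_identical(probeSeqs(back), probeSeqs(probes))
  expect_equal(intensities(back), intensities(probes))
  expect_identical(length(back), 3L)

  bad <- data.frame(id = c("a", "b"), sequence = c(randomDNA(1, 36), "ACGT"),
                    intensity = c(1, 2))
  p2 <- tempfile(); utils::write.table(bad, p2, sep = "\t", row.names = FALSE,
                                       quote = FALSE)
  expect_error(readProbeTable(p2), "2")

  bad2 <- data.frame(id = c("a", "a"),
                     sequence = randomDNA(2, 36), intensity = c(1, 2))
  p3 <- tempfile(); utils::write.table(bad2, p3, sep = "\t", row.names = FALSE,
                                       quote = FALSE)
  expect_error(readProbeTable(p3), "duplicated")

  bad3 <- data.frame(id = c("a", "b"), sequence = randomDNA(2, 36),
                     intensity = c("1.5", "high"))
  p4 <- tempfile(); utils::write.table(bad3, p4, sep = "\t", row.names = FALSE,
                                       quote = FALSE)
  expect_error(readProbeTable(p4), "non-numeric")
})

test_that("normalization is a robust monotone z-score of log intensity", {
  probes <- makeProbes(1000, seed = 3)
  norm <- normalizeIntensities(probes)
  z <- normalizedIntensities(norm)
  expect_equal(cor(intensities(probes), z, method = "spearman"), 1)
  expect_lt(abs(median(z)), 1e-9)

  const <- probeSet(c("a", "b", "c"), randomDNA(3, 36), c(2, 2, 2))
  expect_equal(normalizedIntensities(normalizeIntensities(const)), rep(0, 3))

  neg <- probeSet(c("a", "b", "c"), randomDNA(3, 36), c(-1, 0, 5))
  expect_warning(nn <- normalizeIntensities(neg), "shifted")
  expect_true(all(is.finite(normalizedIntensities(nn))))
  expect_error(normalizeIntensities(probeSet("a", randomDNA(1, 36), 1)),
               "at least 2")
})

test_that("training-probe sampling follows the threshold and top-500 branches", {
  set.seed(5)
  n <- 4000
  z <- rnorm(n)
  z[1:120] <- z[1:120] + 8          # 120 clear outliers
  probes <- probeSet(sprintf("p%04d", 1:n), randomDNA(n, 36), exp(z))
  probes <- normalizeIntensities(probes)

  # fewer qualifying probes than the floor: fall back to the top 500
  s1 <- sampleTrainingProbes(probes, zThreshold = 4, minPositives = 500)
  expect_identical(length(positives(s1)@id), 500L)
  expect_identical(length(negatives(s1)@id), 500L)
  expect_identical(length(sampleLabels(s1)), 1000L)

  # more qualifying probes than the floor: take all of them
  s2 <- sampleTrainingProbes(probes, zThreshold = 1, minPositives = 500)
  nAbove <- sum(normalizedIntensities(probes) >= 1)
  expect_gt(nAbove, 500)
  expect_identical(length(positives(s2)@id), nAbove)
  expect_identical(length(negatives(s2)@id), nAbove)

  # positives dominate negatives and the two tails are extreme
  expect_gte(min(positives(s1)@normalized), max(negatives(s1)@normalized))
  expect_equal(sort(positives(s1)@normalized, decreasing = TRUE),
               sort(normalizedIntensities(probes), decreasing = TRUE)[1:500])

  small <- normalizeIntensities(makeProbes(900, seed = 6))
  expect_error(sampleTrainingProbes(small, minPositives = 500), "degenerate")
  expect_error(sampleTrainingProbes(makeProbes(10), 4), "normalized")
})

test_that("feature selection ranks by class-mean difference with stable ties", {
  p <- diMismatchParams(4, 0, "single")
  # f1 = AAAA occurs in both positives, never in negatives;
  # f2 = CCCC occurs once in each class (zero mean difference)
  pos <- c("AAAACCCC", "AAAAGGGG")
  neg <- c("TGCACCCC", "TGCAGTGG")
  mk <- function(seqs, ids) new("ProbeSet", id = ids, sequence = seqs,
                                intensity = rep(1, 2),
                                normalized = c(1, 1), designId = "t")
  sample <- new("TrainingSample",
                positives = mk(pos, c("p1", "p2")),
                negatives = mk(neg, c("n1", "n2")),
                labels = c(1, 1, -1, -1))
  space <- buildFeatureSpace(c(pos, neg), p)
  top1 <- selectFeatures(sample, space, maxFeatures = 1)
  expect_identical(features(top1), "AAAA")

  # cap is respected; under the cap everything is kept
  all <- selectFeatures(sample, space, maxFeatures = 1000)
  expect_identical(features(all), features(space))
  capped <- selectFeatures(sample, space, maxFeatures = 3)
  expect_identical(length(capped), 3L)
  expect_true(all(features(capped) %in% features(space)))

  # invariance to probe order within a class
  sampleRev <- new("TrainingSample",
                   positives = mk(rev(pos), c("p2", "p1")),
                   negatives = mk(rev(neg), c("n2", "n1")),
                   labels = c(1, 1, -1, -1))
  expect_identical(features(selectFeatures(sampleRev, space, 3)),
                   features(capped))
})

test_that("training samples serialize to FASTA plus labels", {
  probes <- normalizeIntensities(makeProbes(200, seed = 9))
  s <- sampleTrainingProbes(probes, minPositives = 20)
  prefix <- tempfile()
  writeTrainingSample(s, prefix)
  pos <- Biostrings::readDNAStringSet(paste0(prefix, "_pos.fa"))
  lab <- utils::read.delim(paste0(prefix, "_labels.tsv"))
  expect_identical(length(pos), 20L)
  expect_identical(nrow(lab), 40L)
  expect_equal(lab$label, sampleLabels(s))
})
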