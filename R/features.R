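#' Embed model k-mers by alignment to the positive training sequences
#'
#' Represents each k-mer feature by the vector of its best ungapped
#' alignment scores (number of matching positions, over all offsets and -
#' under \code{strandMode = "both"} - both strands) against each positive
#' training sequence. Sequence-similar k-mers obtain nearby vectors because
#' they match the same training examples.
#'
#' @param model a trained \linkS4class{LinearSequenceModel}.
#' @param positiveSequences the positive training sequences (character or
#'   \code{DNAStringSet}).
#' @param kmers the k-mers to embed; defaults to all model features.
#' @return A \linkS4class{FeatureEmbedding}.
#' @export
alignmentScoreVectors <- function(model, positiveSequences,
                                  kmers = features(model@space)) {
  positiveSequences <- .asSeqChar(positiveSequences)
  if (!length(kmers) || !length(positiveSequences)) stop("empty input")
  params <- model@config@params
  w <- modelWeights(model)[kmers]
  if (anyNA(w)) stop("all k-mers must be model features")
  vec <- cpp_alignment_scores(kmers, positiveSequences,
                              params@strandMode == "both")
  rownames(vec) <- kmers
  new("FeatureEmbedding", kmers = kmers, vectors = vec,
      weights = as.numeric(w), params = params)
}

setMethod("show", "FeatureEmbedding", function(object) {
  cat(sprintf("FeatureEmbedding: %d k-mers x %d positive sequences\n",
              length(object@kmers), ncol(object@vectors)))
})

#' Cluster the k-mer features of a trained model
#'
#' Runs k-means (2 clusters by default, seeded, multiple restarts) on the
#' alignment-score vectors, keeps the \code{topPerCluster} k-mers of each
#' cluster by model weight, and projects the kept set to two dimensions by
#' principal component analysis. Well-separated clusters typically expose a
#' primary and a secondary (or cofactor) motif.
#'
#' @param embedding a \linkS4class{FeatureEmbedding}.
#' @param topPerCluster k-mers kept per cluster for the projection (500 in
#'   the standard analysis).
#' @param nClusters number of clusters.
#' @param seed k-means seed.
#' @return A \linkS4class{ClusterReport} (expanded PSSMs are filled by
#'   \code{\link{expandFeatureToPSSM}}).
#' @export
clusterModelFeatures <- function(embedding, topPerCluster = 500,
                                 nClusters = 2, seed = 1) {
  V <- embedding@vectors
  if (nrow(V) < 2L * nClusters)
    stop("need at least ", 2L * nClusters, " k-mers")
  if (all(apply(V, 2L, function(x) length(unique(x))) == 1L))
    stop("degenerate clustering: all alignment vectors identical")
  set.seed(seed)
  km <- stats::kmeans(V, centers = nClusters, nstart = 10)
  assignment <- stats::setNames(as.integer(km$cluster), embedding@kmers)
  weights <- stats::setNames(embedding@weights, embedding@kmers)
  kept <- unlist(lapply(seq_len(nClusters), function(cl) {
    members <- embedding@kmers[assignment == cl]
    members[order(-weights[members], members)][
      seq_len(min(topPerCluster, length(members)))]
  }), use.names = FALSE)
  pca <- stats::prcomp(V[kept, , drop = FALSE], center = TRUE, scale. = FALSE)
  proj <- pca$x[, seq_len(min(2L, ncol(pca$x))), drop = FALSE]
  report <- new("ClusterReport", assignment = assignment, kept = kept,
                projection = proj, weights = weights, centers = km$centers,
                representatives = character(0))
  report@representatives <- selectClusterRepresentative(report, embedding)
  report
}

setMethod("show", "ClusterReport", function(object) {
  k <- nrow(object@centers)
  cat(sprintf("ClusterReport: %d k-mers in %d clusters (%s kept for projection)\n",
              length(object@assignment), k, length(object@kept)))
  if (length(object@representatives))
    cat("  representatives:", paste(object@representatives, collapse = ", "), "\n")
})

#' Pick a representative k-mer per cluster
#'
#' The representative is the cluster member that (i) lies in the top
#' quartile of the model weights within its cluster and (ii) among those is
#' nearest (Euclidean, in alignment-vector space) to the cluster centroid.
#' Ties break lexicographically.
#'
#' @param report a \linkS4class{ClusterReport}.
#' @param embedding the \linkS4class{FeatureEmbedding} the report was built
#'   from.
#' @return Character vector, one k-mer per cluster.
#' @export
selectClusterRepresentative <- function(report, embedding) {
  V <- embedding@vectors
  vapply(seq_len(nrow(report@centers)), function(cl) {
    members <- names(report@assignment)[report@assignment == cl]
    w <- report@weights[members]
    cand <- members[w >= stats::quantile(w, 0.75)]
    d <- sqrt(colSums((t(V[cand, , drop = FALSE]) - report@centers[cl, ])^2))
    cand[order(d, cand)][1L]
  }, character(1))
}

#' Expand a k-mer feature into a PSSM
#'
#' Takes the \code{topN} positive training sequences that best align to the
#' k-mer, extracts from each the k-length window achieving the optimal
#' ungapped alignment (oriented to the strand achieving the maximum), stacks
#' the windows into a position frequency matrix and converts to
#' probabilities with a pseudocount.
#'
#' @param kmer the feature to expand.
#' @param positiveSequences positive training sequences.
#' @param topN number of best-aligned sequences to use (50 in the standard
#'   analysis).
#' @param pseudocount added per base before normalizing.
#' @param bothStrands consider reverse-complement alignments.
#' @return A \linkS4class{PSSM} of the k-mer's width.
#' @export
expandFeatureToPSSM <- function(kmer, positiveSequences, topN = 50,
                                pseudocount = 0.01, bothStrands = TRUE) {
  positiveSequences <- .asSeqChar(positiveSequences)
  if (length(positiveSequences) < topN)
    stop("need at least ", topN, " positive sequences")
  k <- nchar(kmer)
  aln <- cpp_align_best(toupper(kmer), positiveSequences, bothStrands)
  ord <- order(-aln[, 1L], seq_len(nrow(aln)))[seq_len(topN)]
  windows <- vapply(ord, function(i) {
    wnd <- substr(positiveSequences[i], aln[i, 2L] + 1L, aln[i, 2L] + k)
    if (aln[i, 3L] == 1L) as.character(cpp_revcomp(wnd)) else wnd
  }, character(1))
  counts <- matrix(0, nrow = k, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  chars <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                  nrow = length(windows), byrow = TRUE)
  for (j in seq_len(k)) {
    tb <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
    counts[j, ] <- as.numeric(tb)
  }
  probs <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
  pssm(probs / rowSums(probs), pseudocount = pseudocount)
}

#' Retrain on a subset of k-mer features
#'
#' Restricts the feature space to the given k-mers and retrains; used to
#' quantify how much each feature cluster contributes to in vivo prediction
#' (e.g. retraining on the primary-motif cluster versus the secondary one).
#'
#' @param sample a \linkS4class{TrainingSample} (regression) or
#'   \linkS4class{LabeledWindowSet} (classification).
#' @param kmers non-empty set of k-mer features.
#' @param config \linkS4class{TrainingConfig}; its mode must match the
#'   sample type.
#' @return A \linkS4class{LinearSequenceModel}.
#' @export
retrainOnFeatureSubset <- function(sample, kmers, config = trainingConfig()) {
  if (!length(kmers)) stop("empty feature subset")
  space <- new("FeatureSpace", features = sort(unique(toupper(kmers))),
               params = config@params)
  if (methods::is(sample, "TrainingSample")) {
    if (config@mode != "regression")
      stop("a TrainingSample requires mode = 'regression'")
    trainRegressor(sample, config, space = space)
  } else if (methods::is(sample, "LabeledWindowSet")) {
    if (config@mode != "classification")
      stop("a LabeledWindowSet requires mode = 'classification'")
    trainClassifier(sample, config, space = space)
  } else stop("unsupported sample type")
}

#' Write a cluster report as TSV
#'
#' One row per kept k-mer: k-mer, cluster, model weight and the two PCA
#' coordinates.
#'
#' @param report a \linkS4class{ClusterReport}.
#' @param path output file.
#' @export
writeClusterReport <- function(report, path) {
  kept <- report@kept
  utils::write.table(
    data.frame(kmer = kept, cluster = report@assignment[kept],
               weight = report@weights[kept],
               x = report@projection[, 1L],
               y = if (ncol(report@projection) > 1L) report@projection[, 2L] else 0,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
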