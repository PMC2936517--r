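#' @import methods
NULL

#' Di-mismatch kernel hyperparameters
#'
#' Holds the k-mer length \code{k}, the maximum tolerated number \code{m} of
#' mismatching dinucleotides, and the strand mode. The match threshold is
#' derived: a pair of k-mers scores 0 unless at least \code{k - 1 - m} of
#' their \code{k - 1} overlapping dinucleotides agree. With the standard
#' choice (13, 5) two 13-mers must share at least 8 matching dinucleotides
#' (hence at least 8 matching characters) to contribute.
#'
#' @slot k integer k-mer length (2..16; the kernel packs the k-1 dinucleotide
#'   codes of a k-mer into a single 64-bit word).
#' @slot m integer, maximum number of mismatching dinucleotides tolerated.
#' @slot strandMode \code{"both"} (double-stranded DNA; the score of a window
#'   against a feature is the maximum over the feature and its reverse
#'   complement) or \code{"single"}.
#' @export
setClass("DiMismatchParams",
  representation(k = "integer", m = "integer", strandMode = "character"),
  prototype(k = 13L, m = 5L, strandMode = "both"))

setValidity("DiMismatchParams", function(object) {
  msg <- character()
  if (length(object@k) != 1L || is.na(object@k) || object@k < 2L)
    msg <- c(msg, "'k' must be a single integer >= 2")
  if (length(object@k) == 1L && !is.na(object@k) && object@k > 16L)
    msg <- c(msg, "'k' must be <= 16 (packed 64-bit representation)")
  if (length(object@m) != 1L || is.na(object@m) ||
      object@m < 0L || object@m > object@k - 1L)
    msg <- c(msg, "'m' must satisfy 0 <= m <= k - 1")
  if (!(object@strandMode %in% c("single", "both")))
    msg <- c(msg, "'strandMode' must be \"single\" or \"both\"")
  if (length(msg)) msg else TRUE
})

#' Dictionary of k-mer features
#'
#' An ordered (lexicographic) set of distinct k-mers over ACGT. Under
#' \code{strandMode = "both"} every feature is stored in canonical form (the
#' lexicographically smaller of the k-mer and its reverse complement), so no
#' feature is the reverse complement of another.
#'
#' @slot features character vector of k-mers.
#' @slot params the \linkS4class{DiMismatchParams} the space was built under.
#' @export
setClass("FeatureSpace",
  representation(features = "character", params = "DiMismatchParams"))

setValidity("FeatureSpace", function(object) {
  msg <- character()
  f <- object@features
  if (length(f) == 0L) msg <- c(msg, "feature space is empty")
  if (anyDuplicated(f)) msg <- c(msg, "features must be unique")
  if (is.unsorted(f)) msg <- c(msg, "features must be in lexicographic order")
  if (length(f) && any(nchar(f) != object@params@k))
    msg <- c(msg, "all features must have length k")
  if (length(f) && object@params@strandMode == "both") {
    rc <- cpp_revcomp(f)
    if (any(rc < f)) msg <- c(msg, "features must be strand-canonical under strandMode \"both\"")
  }
  if (length(msg)) msg else TRUE
})

#' A set of PBM probes
#'
#' Probe identifiers, fixed-length probe sequences (the 36-nt variable region
#' of a standard PBM probe) and raw fluorescence intensities, with an optional
#' normalized-intensity track added by \code{\link{normalizeIntensities}}.
#'
#' @slot id character probe identifiers (unique).
#' @slot sequence character probe sequences, all of equal length.
#' @slot intensity numeric raw intensities (finite).
#' @slot normalized numeric, empty until normalization.
#' @slot designId character(1) array-design label.
#' @export
setClass("ProbeSet",
  representation(id = "character", sequence = "character",
                 intensity = "numeric", normalized = "numeric",
                 designId = "character"),
  prototype(normalized = numeric(0), designId = "design"))

setValidity("ProbeSet", function(object) {
  msg <- character()
  n <- length(object@id)
  if (anyDuplicated(object@id)) msg <- c(msg, "probe ids must be unique")
  if (length(object@sequence) != n || length(object@intensity) != n)
    msg <- c(msg, "id, sequence and intensity must have equal length")
  if (n && length(unique(nchar(object@sequence))) != 1L)
    msg <- c(msg, "all probe sequences must have the same length")
  if (any(!is.finite(object@intensity)))
    msg <- c(msg, "intensities must be finite")
  if (length(object@normalized) && length(object@normalized) != n)
    msg <- c(msg, "normalized track must match the number of probes")
  if (length(msg)) msg else TRUE
})

#' An informative PBM training sample
#'
#' Equal numbers of high-intensity ("positive") and low-intensity ("negative")
#' probes drawn from the tails of the normalized-intensity distribution, with
#' per-probe regression labels (their normalized intensities).
#'
#' @slot positives,negatives \linkS4class{ProbeSet} objects of equal size.
#' @slot labels numeric, one label per probe (positives first).
#' @export
setClass("TrainingSample",
  representation(positives = "ProbeSet", negatives = "ProbeSet",
                 labels = "numeric"))

setValidity("TrainingSample", function(object) {
  msg <- character()
  np <- length(object@positives@id)
  nn <- length(object@negatives@id)
  if (np != nn) msg <- c(msg, "positives and negatives must have equal size")
  if (length(object@labels) != np + nn)
    msg <- c(msg, "labels must cover positives then negatives")
  if (length(intersect(object@positives@id, object@negatives@id)))
    msg <- c(msg, "positives and negatives must be disjoint")
  if (np && nn && length(object@positives@normalized) &&
      length(object@negatives@normalized) &&
      min(object@positives@normalized) < max(object@negatives@normalized))
    msg <- c(msg, "every positive must score at least every negative")
  if (length(msg)) msg else TRUE
})

#' Training configuration for di-mismatch models
#'
#' @slot epsilon numeric, the epsilon-insensitive tube width of the SVR
#'   (fixed at 0.1 in all standard runs).
#' @slot cost numeric, the soft-margin regularization constant C.
#' @slot params \linkS4class{DiMismatchParams}.
#' @slot maxFeatures integer cap on the number of selected k-mer features.
#' @slot mode \code{"regression"} (PBM intensities) or \code{"classification"}
#'   (ChIP peak vs flank).
#' @export
setClass("TrainingConfig",
  representation(epsilon = "numeric", cost = "numeric",
                 params = "DiMismatchParams", maxFeatures = "integer",
                 mode = "character"))

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (!(object@mode %in% c("regression", "classification")))
    msg <- c(msg, "'mode' must be \"regression\" or \"classification\"")
  if (object@mode == "regression" && object@epsilon <= 0)
    msg <- c(msg, "'epsilon' must be positive for regression")
  if (object@cost <= 0) msg <- c(msg, "'cost' must be positive")
  if (object@maxFeatures < 1L) msg <- c(msg, "'maxFeatures' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' A trained linear sequence model
#'
#' The solution of an SVR/SVM in the explicit di-mismatch feature space: one
#' weight per k-mer feature plus a bias. A sequence's prediction is
#' \code{weights . featureMap(sequence) + bias}.
#'
#' @slot space \linkS4class{FeatureSpace}.
#' @slot weights numeric, one per feature.
#' @slot bias numeric(1).
#' @slot config \linkS4class{TrainingConfig}.
#' @slot provenance character(1) free-text training record.
#' @export
setClass("LinearSequenceModel",
  representation(space = "FeatureSpace", weights = "numeric",
                 bias = "numeric", config = "TrainingConfig",
                 provenance = "character"),
  prototype(provenance = ""))

setValidity("LinearSequenceModel", function(object) {
  msg <- character()
  if (length(object@weights) != length(object@space@features))
    msg <- c(msg, "one weight per feature is required")
  if (length(object@bias) != 1L || !is.finite(object@bias))
    msg <- c(msg, "'bias' must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Labeled 60-bp ChIP windows
#'
#' @slot sequences character windows (all of equal length, 60 nt in the
#'   standard pipeline).
#' @slot labels integer, +1 for peak-centered windows, -1 for flanks.
#' @slot origin character \code{"chrom:start-end"} provenance per window.
#' @export
setClass("LabeledWindowSet",
  representation(sequences = "character", labels = "integer",
                 origin = "character"))

setValidity("LabeledWindowSet", function(object) {
  msg <- character()
  n <- length(object@sequences)
  if (length(object@labels) != n || length(object@origin) != n)
    msg <- c(msg, "sequences, labels and origin must have equal length")
  if (n && length(unique(nchar(object@sequences))) != 1L)
    msg <- c(msg, "all windows must have the same length")
  if (any(!(object@labels %in% c(-1L, 1L))))
    msg <- c(msg, "labels must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' A ranked set of ChIP peaks
#'
#' @slot chrom character chromosome per peak.
#' @slot summit integer 0-based summit coordinate.
#' @slot score numeric peak score (e.g. read enrichment).
#' @slot ranked logical(1), TRUE if scores are non-increasing.
#' @export
setClass("PeakSet",
  representation(chrom = "character", summit = "integer", score = "numeric",
                 ranked = "logical"))

setValidity("PeakSet", function(object) {
  msg <- character()
  n <- length(object@chrom)
  if (length(object@summit) != n || length(object@score) != n)
    msg <- c(msg, "chrom, summit and score must have equal length")
  if (any(object@summit < 0L)) msg <- c(msg, "summits must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Position-specific scoring matrix
#'
#' Per-position base probabilities (rows are positions, columns A, C, G, T),
#' a background distribution and a pseudocount used when taking log-odds.
#'
#' @slot probs numeric matrix, width x 4, rows summing to one.
#' @slot background numeric(4) summing to one.
#' @slot pseudocount numeric(1) >= 0.
#' @export
setClass("PSSM",
  representation(probs = "matrix", background = "numeric",
                 pseudocount = "numeric"))

setValidity("PSSM", function(object) {
  msg <- character()
  if (ncol(object@probs) != 4L) msg <- c(msg, "'probs' must have 4 columns (A,C,G,T)")
  if (nrow(object@probs) < 1L) msg <- c(msg, "'probs' must have at least one position")
  if (any(abs(rowSums(object@probs) - 1) > 1e-9))
    msg <- c(msg, "each position must sum to 1")
  if (length(object@background) != 4L || abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "'background' must be 4 probabilities summing to 1")
  if (object@pseudocount < 0) msg <- c(msg, "'pseudocount' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Table of 8-mer enrichment scores
#'
#' Rank-based enrichment (E-) scores in [-0.5, 0.5] for strand-merged
#' contiguous 8-mers, computed from a PBM probe ranking.
#'
#' @slot scores named numeric, one score per canonical 8-mer.
#' @slot width integer(1) pattern width (8).
#' @slot sourceDesign character(1).
#' @export
setClass("EScoreTable",
  representation(scores = "numeric", width = "integer",
                 sourceDesign = "character"),
  prototype(width = 8L, sourceDesign = ""))

setValidity("EScoreTable", function(object) {
  msg <- character()
  if (length(object@scores) && is.null(names(object@scores)))
    msg <- c(msg, "scores must be named by 8-mer")
  if (length(object@scores) &&
      (min(object@scores) < -0.5 - 1e-12 || max(object@scores) > 0.5 + 1e-12))
    msg <- c(msg, "scores must lie in [-0.5, 0.5]")
  if (length(msg)) msg else TRUE
})

#' A sliding-window binding profile over one region
#'
#' @slot regionId character(1).
#' @slot scores numeric, one model score per window.
#' @slot windowLength integer(1).
#' @slot stride integer(1).
#' @slot regionStart integer(1) 0-based genomic start of the region (for
#'   bedGraph export); 0 when unknown.
#' @export
setClass("BindingProfile",
  representation(regionId = "character", scores = "numeric",
                 windowLength = "integer", stride = "integer",
                 regionStart = "integer"),
  prototype(regionStart = 0L))

#' Alignment-score embedding of model k-mers
#'
#' Each k-mer feature is represented by the vector of its best ungapped
#' alignment scores (number of matching positions) against the positive
#' training sequences; nearby vectors indicate k-mers supported by the same
#' probes/peaks.
#'
#' @slot kmers character.
#' @slot vectors integer matrix, k-mers x positive sequences, entries in
#'   [0, k].
#' @slot weights numeric model weight per k-mer.
#' @slot params \linkS4class{DiMismatchParams} (strand mode governs whether
#'   reverse-complement alignments are considered).
#' @export
setClass("FeatureEmbedding",
  representation(kmers = "character", vectors = "matrix",
                 weights = "numeric", params = "DiMismatchParams"))

setValidity("FeatureEmbedding", function(object) {
  msg <- character()
  if (nrow(object@vectors) != length(object@kmers))
    msg <- c(msg, "one alignment vector per k-mer is required")
  if (length(object@weights) != length(object@kmers))
    msg <- c(msg, "one weight per k-mer is required")
  if (length(msg)) msg else TRUE
})

#' Two-cluster dissection of a trained model's k-mer features
#'
#' @slot assignment named integer cluster label (1..nClusters) per k-mer.
#' @slot kept character, the k-mers retained for projection (top weights per
#'   cluster).
#' @slot projection numeric matrix (kept k-mers x 2), PCA coordinates.
#' @slot weights named numeric model weights of all clustered k-mers.
#' @slot centers numeric matrix of cluster centroids in alignment space.
#' @slot representatives character, one k-mer per cluster (top-quartile
#'   weight, nearest the centroid).
#' @slot expandedPssms list of \linkS4class{PSSM}, one per cluster (possibly
#'   empty until expansion).
#' @export
setClass("ClusterReport",
  representation(assignment = "integer", kept = "character",
                 projection = "matrix", weights = "numeric",
                 centers = "matrix", representatives = "character",
                 expandedPssms = "list"),
  prototype(expandedPssms = list()))

#' Specification of a synthetic PBM / ChIP experiment
#'
#' Defines the seeded generative model used throughout the test suites: probe
#' sequences are uniform random; a fraction carries a site sampled from a
#' planted PSSM; log-intensity is the sum over probe windows of a softplus of
#' the PSSM log-odds, scaled by the effect size, plus Gaussian noise.
#'
#' @slot seed integer(1).
#' @slot nProbes integer probes per array design.
#' @slot probeLength integer(1).
#' @slot plantedPssms list of \linkS4class{PSSM}.
#' @slot effectSizes numeric, one per planted PSSM.
#' @slot noiseSd numeric(1) Gaussian noise SD on the log-intensity scale.
#' @slot chemicalPotential numeric(1) offset subtracted from the window
#'   log-odds before the softplus, so that sub-site partial matches
#'   contribute essentially nothing and only a few hundred probes per design
#'   show binding.
#' @slot plantFraction numeric(1) in (0, 1).
#' @slot genomeLength,nPeaks integer, ChIP-side dimensions.
#' @slot cofactor list; empty, or a single \linkS4class{PSSM} planted in a
#'   fraction of positive windows.
#' @slot cofactorFraction numeric(1) in [0, 1].
#' @slot cofactorMode \code{"beside"} (cofactor next to the primary site) or
#'   \code{"instead"} (cofactor replaces the primary site).
#' @export
setClass("SyntheticSpec",
  representation(seed = "integer", nProbes = "integer", probeLength = "integer",
                 plantedPssms = "list", effectSizes = "numeric",
                 noiseSd = "numeric", chemicalPotential = "numeric",
                 plantFraction = "numeric",
                 genomeLength = "integer", nPeaks = "integer",
                 cofactor = "list", cofactorFraction = "numeric",
                 cofactorMode = "character"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@plantFraction <= 0 || object@plantFraction >= 1)
    msg <- c(msg, "'plantFraction' must be in (0, 1)")
  if (length(object@effectSizes) != length(object@plantedPssms))
    msg <- c(msg, "one effect size per planted PSSM is required")
  if (any(object@effectSizes < 0)) msg <- c(msg, "effect sizes must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (length(object@cofactor) > 1L)
    msg <- c(msg, "'cofactor' must be empty or a single PSSM")
  if (object@cofactorFraction < 0 || object@cofactorFraction > 1)
    msg <- c(msg, "'cofactorFraction' must be in [0, 1]")
  if (!(object@cofactorMode %in% c("beside", "instead")))
    msg <- c(msg, "'cofactorMode' must be \"beside\" or \"instead\"")
  if (length(msg)) msg else TRUE
})
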