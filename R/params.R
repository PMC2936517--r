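#' Create di-mismatch kernel parameters
#'
#' @param k k-mer length (2..16).
#' @param m maximum number of mismatching dinucleotides tolerated before a
#'   pair of k-mers scores zero; the derived match threshold is
#'   \code{k - 1 - m}.
#' @param strandMode \code{"both"} (default; double-stranded scoring) or
#'   \code{"single"}.
#' @return A \linkS4class{DiMismatchParams} object.
#' @examples
#' p <- diMismatchParams(13, 5)
#' minMatchingDinucs(p)  # 7
#' @export
diMismatchParams <- function(k = 13, m = 5, strandMode = c("both", "single")) {
  strandMode <- match.arg(strandMode)
  new("DiMismatchParams", k = as.integer(k), m = as.integer(m),
      strandMode = strandMode)
}

#' @describeIn diMismatchParams k-mer length.
#' @param params a \linkS4class{DiMismatchParams}.
#' @export
kmerLength <- function(params) params@k

#' @describeIn diMismatchParams maximum tolerated mismatching dinucleotides.
#' @export
maxMismatches <- function(params) params@m

#' @describeIn diMismatchParams the derived threshold \code{k - 1 - m}: the
#'   minimum number of matching dinucleotides for a non-zero score.
#' @export
minMatchingDinucs <- function(params) params@k - 1L - params@m

#' @describeIn diMismatchParams strand mode in use.
#' @export
strandMode <- function(params) params@strandMode

setMethod("show", "DiMismatchParams", function(object) {
  cat(sprintf("DiMismatchParams: k = %d, m = %d (>= %d matching dinucleotides), strand = %s\n",
              object@k, object@m, minMatchingDinucs(object), object@strandMode))
})

#' Create a training configuration
#'
#' @param epsilon SVR tube width; 0.1 in all standard runs.
#' @param cost soft-margin constant C (not pinned by the training protocol;
#'   defaults to 1).
#' @param params \linkS4class{DiMismatchParams}; the standard model choice is
#'   (13, 5), which requires at least 8 matching characters between k-mers.
#' @param maxFeatures cap on the number of selected k-mer features (4000 in
#'   all standard runs).
#' @param mode \code{"regression"} for PBM intensities, \code{"classification"}
#'   for ChIP peak-vs-flank windows.
#' @return A \linkS4class{TrainingConfig}.
#' @export
trainingConfig <- function(epsilon = 0.1, cost = 1,
                           params = diMismatchParams(),
                           maxFeatures = 4000,
                           mode = c("regression", "classification")) {
  mode <- match.arg(mode)
  new("TrainingConfig", epsilon = as.numeric(epsilon), cost = as.numeric(cost),
      params = params, maxFeatures = as.integer(maxFeatures), mode = mode)
}

setMethod("show", "TrainingConfig", function(object) {
  cat(sprintf("TrainingConfig: mode = %s, epsilon = %g, C = %g, maxFeatures = %d\n",
              object@mode, object@epsilon, object@cost, object@maxFeatures))
  show(object@params)
})

#' @describeIn featureSpaceAccessors the k-mer features, in lexicographic order.
#' @export
features <- function(space) space@features

#' Feature space accessors
#'
#' @name featureSpaceAccessors
#' @param space a \linkS4class{FeatureSpace}.
#' @return \code{features}: character vector; \code{kernelParams}: the
#'   \linkS4class{DiMismatchParams} the space was built under.
NULL

#' @describeIn featureSpaceAccessors the kernel parameters of the space.
#' @export
kernelParams <- function(space) space@params

setMethod("length", "FeatureSpace", function(x) length(x@features))

setMethod("show", "FeatureSpace", function(object) {
  cat(sprintf("FeatureSpace: %d %d-mer features (%s strand)\n",
              length(object@features), object@params@k, object@params@strandMode))
  n <- min(5L, length(object@features))
  if (n) cat("  ", paste(object@features[seq_len(n)], collapse = " "),
             if (length(object@features) > n) "..." else "", "\n")
})

#' Probe set accessors
#'
#' @name probeSetAccessors
#' @param probes a \linkS4class{ProbeSet}.
NULL

#' @describeIn probeSetAccessors probe identifiers.
#' @export
probeIds <- function(probes) probes@id

#' @describeIn probeSetAccessors probe sequences (character).
#' @export
probeSeqs <- function(probes) probes@sequence

#' @describeIn probeSetAccessors raw intensities.
#' @export
intensities <- function(probes) probes@intensity

#' @describeIn probeSetAccessors normalized intensities (empty before
#'   \code{\link{normalizeIntensities}}).
#' @export
normalizedIntensities <- function(probes) probes@normalized

#' @describeIn probeSetAccessors array-design label.
#' @export
designId <- function(probes) probes@designId

setMethod("length", "ProbeSet", function(x) length(x@id))

setMethod("show", "ProbeSet", function(object) {
  cat(sprintf("ProbeSet '%s': %d probes of length %d%s\n",
              object@designId, length(object@id),
              if (length(object@id)) nchar(object@sequence[1L]) else 0L,
              if (length(object@normalized)) " (normalized)" else ""))
})

#' Construct a ProbeSet
#'
#' @param id,sequence,intensity parallel probe vectors.
#' @param designId array-design label.
#' @return A \linkS4class{ProbeSet}. Sequences are uppercased.
#' @export
probeSet <- function(id, sequence, intensity, designId = "design") {
  new("ProbeSet", id = as.character(id), sequence = toupper(as.character(sequence)),
      intensity = as.numeric(intensity), designId = designId)
}

#' @describeIn trainingSampleAccessors the positive (high-intensity) probes.
#' @export
positives <- function(sample) sample@positives

#' Training sample accessors
#'
#' @name trainingSampleAccessors
#' @param sample a \linkS4class{TrainingSample}.
NULL

#' @describeIn trainingSampleAccessors the negative (low-intensity) probes.
#' @export
negatives <- function(sample) sample@negatives

#' @describeIn trainingSampleAccessors regression labels (positives first).
#' @export
sampleLabels <- function(sample) sample@labels

setMethod("show", "TrainingSample", function(object) {
  cat(sprintf("TrainingSample: %d positives + %d negatives\n",
              length(object@positives@id), length(object@negatives@id)))
})

#' Linear model accessors
#'
#' @name modelAccessors
#' @param model a \linkS4class{LinearSequenceModel}.
NULL

#' @describeIn modelAccessors the per-feature weight vector (named by k-mer).
#' @export
modelWeights <- function(model) {
  stats::setNames(model@weights, model@space@features)
}

#' @describeIn modelAccessors the bias term.
#' @export
modelBias <- function(model) model@bias

#' @describeIn modelAccessors the model's \linkS4class{FeatureSpace}.
#' @export
featureSpace <- function(model) model@space

#' @describeIn modelAccessors the \linkS4class{TrainingConfig} used.
#' @export
modelConfig <- function(model) model@config

setMethod("show", "LinearSequenceModel", function(object) {
  cat(sprintf("LinearSequenceModel (%s): %d features, bias %.4g\n",
              object@config@mode, length(object@weights), object@bias))
  if (nzchar(object@provenance)) cat("  provenance:", object@provenance, "\n")
})

#' Construct a labeled window set
#'
#' @param sequences equal-length window sequences.
#' @param labels +1 / -1 per window.
#' @param origin optional \code{"chrom:start-end"} provenance strings.
#' @export
labeledWindowSet <- function(sequences, labels, origin = NULL) {
  if (is.null(origin)) origin <- rep("", length(sequences))
  new("LabeledWindowSet", sequences = toupper(as.character(sequences)),
      labels = as.integer(labels), origin = as.character(origin))
}

#' @describeIn labeledWindowSet the window sequences.
#' @param windows a \linkS4class{LabeledWindowSet}.
#' @export
windowSeqs <- function(windows) windows@sequences

#' @describeIn labeledWindowSet the +1/-1 labels.
#' @export
windowLabels <- function(windows) windows@labels

setMethod("length", "LabeledWindowSet", function(x) length(x@sequences))

setMethod("show", "LabeledWindowSet", function(object) {
  cat(sprintf("LabeledWindowSet: %d windows (%d positive, %d negative) of length %d\n",
              length(object@sequences), sum(object@labels == 1L),
              sum(object@labels == -1L),
              if (length(object@sequences)) nchar(object@sequences[1L]) else 0L))
})

#' Construct a peak set
#'
#' @param chrom,summit,score parallel vectors; summits are 0-based.
#' @export
peakSet <- function(chrom, summit, score = rev(seq_along(chrom))) {
  new("PeakSet", chrom = as.character(chrom), summit = as.integer(summit),
      score = as.numeric(score), ranked = !is.unsorted(rev(score)))
}

setMethod("length", "PeakSet", function(x) length(x@chrom))

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %d peaks on %d sequence(s)%s\n", length(object@chrom),
              length(unique(object@chrom)),
              if (isTRUE(object@ranked)) ", ranked" else ""))
})
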