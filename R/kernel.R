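.checkKmers <- function(x, k, what = "k-mer") {
  bad <- which(nchar(x) != k)
  if (length(bad))
    stop(sprintf("%s '%s' does not have length %d", what, x[bad[1L]], k))
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(sprintf("%s '%s' contains a non-ACGT character", what, x[which(bad)[1L]]))
  invisible(TRUE)
}

.asSeqChar <- function(x) {
  if (methods::is(x, "XStringSet") || methods::is(x, "XString"))
    x <- as.character(x)
  toupper(as.character(x))
}

#' Di-mismatch score between k-mers
#'
#' Counts the matching overlapping dinucleotides between two k-mers (the
#' \code{k - 1} dinucleotides at offsets 1..k-1). The count is set to zero if
#' it falls below the threshold \code{k - 1 - m}, so a pair with more than
#' \code{m} mismatching dinucleotides contributes nothing. Under
#' \code{strandMode = "both"} the score is the maximum of the score against
#' \code{b} and against its reverse complement.
#'
#' A single substituted nucleotide disrupts up to two overlapping
#' dinucleotides, but consecutive substitutions share dinucleotides, so the
#' kernel inherently favors k-mer pairs whose mismatches are consecutive:
#' four consecutive interior mismatches cost 5 mismatching dinucleotides,
#' while four isolated mismatches can cost up to 8.
#'
#' @param a,b character vectors of k-mers (recycled pairwise, equal length).
#' @param params \linkS4class{DiMismatchParams}.
#' @return Integer vector of thresholded matching-dinucleotide counts.
#' @examples
#' p <- diMismatchParams(4, 1, "single")
#' diMismatchScore("ACGT", "ACGA", p)  # 2
#' @export
diMismatchScore <- function(a, b, params = diMismatchParams()) {
  a <- .asSeqChar(a); b <- .asSeqChar(b)
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  .checkKmers(a, params@k)
  .checkKmers(b, params@k)
  cpp_score_pairs(a, b, params@k, minMatchingDinucs(params),
                  params@strandMode == "both")
}

#' Build the k-mer feature dictionary of a sequence set
#'
#' Enumerates the distinct k-mers occurring as substrings of the input
#' (typically the training probe or window sequences). Windows containing
#' non-ACGT characters are skipped. Under \code{strandMode = "both"} each
#' k-mer is replaced by its strand-canonical form (the lexicographically
#' smaller of the k-mer and its reverse complement) so that no feature is the
#' reverse complement of another. Features are returned in lexicographic
#' order.
#'
#' @param sequences character vector or \code{DNAStringSet}.
#' @param params \linkS4class{DiMismatchParams}.
#' @return A \linkS4class{FeatureSpace}.
#' @export
buildFeatureSpace <- function(sequences, params = diMismatchParams()) {
  sequences <- .asSeqChar(sequences)
  if (!length(sequences)) stop("no input sequences")
  if (all(nchar(sequences) < params@k))
    stop("all sequences are shorter than k")
  feats <- cpp_unique_kmers(sequences, params@k, params@strandMode == "both")
  if (!length(feats))
    stop("no valid k-mers found in the input sequences")
  new("FeatureSpace", features = feats, params = params)
}

#' Di-mismatch feature map
#'
#' Maps each sequence to its explicit di-mismatch feature vector: the entry
#' for feature \code{f} is the sum, over all length-k windows of the
#' sequence, of the (thresholded) di-mismatch score between the window and
#' \code{f}. Windows containing non-ACGT characters contribute zero.
#'
#' @param sequences character vector or \code{DNAStringSet}, each of length
#'   at least k.
#' @param space \linkS4class{FeatureSpace}.
#' @return Numeric matrix, sequences x features (column names are the
#'   feature k-mers).
#' @export
featureMap <- function(sequences, space) {
  sequences <- .asSeqChar(sequences)
  params <- space@params
  if (any(nchar(sequences) < params@k)) stop("sequence shorter than k")
  m <- cpp_feature_map(sequences, space@features, params@k,
                       minMatchingDinucs(params),
                       params@strandMode == "both")
  colnames(m) <- space@features
  m
}

#' Di-mismatch kernel matrix
#'
#' Inner products of explicit di-mismatch feature vectors. For \code{X = Y}
#' the result is a symmetric positive semi-definite Gram matrix.
#'
#' @param X,Y sequence sets (character or \code{DNAStringSet}); \code{Y}
#'   defaults to \code{X}.
#' @param space \linkS4class{FeatureSpace}.
#' @return Numeric matrix, \code{length(X)} x \code{length(Y)}.
#' @export
diKernelMatrix <- function(X, Y = NULL, space) {
  mx <- featureMap(X, space)
  if (is.null(Y)) return(tcrossprod(mx))
  my <- featureMap(Y, space)
  tcrossprod(mx, my)
}

#' Precomputed k-mer contribution table
#'
#' For a trained linear model, the contribution of a window k-mer \code{u} is
#' \code{sum_f weight[f] * diMismatchScore(u, f)}. Contributions can be
#' computed once per distinct k-mer and cached, which makes scoring a
#' sequence of length L a sum of L - k + 1 table lookups plus the bias;
#' \code{\link{predictScores}} and \code{\link{scanSequence}} use exactly
#' this path internally.
#'
#' @param model \linkS4class{LinearSequenceModel}.
#' @param kmers k-mers to tabulate; defaults to the model's own features.
#' @return Named numeric vector of contributions.
#' @export
kmerContributionTable <- function(model, kmers = features(model@space)) {
  kmers <- .asSeqChar(kmers)
  params <- model@config@params
  .checkKmers(kmers, params@k)
  stats::setNames(
    cpp_kmer_contribs(kmers, model@space@features, model@weights, params@k,
                      minMatchingDinucs(params), params@strandMode == "both"),
    kmers)
}

#' Write / read a feature space as plain text
#'
#' One k-mer per line, preceded by a header line
#' \code{# k=<k> m=<m> strand=<mode>}.
#'
#' @param space a \linkS4class{FeatureSpace}.
#' @param path file path.
#' @return \code{readFeatureSpace} returns a \linkS4class{FeatureSpace}.
#' @export
writeFeatureSpace <- function(space, path) {
  p <- space@params
  writeLines(c(sprintf("# k=%d m=%d strand=%s", p@k, p@m, p@strandMode),
               space@features), path)
  invisible(path)
}

#' @rdname writeFeatureSpace
#' @export
readFeatureSpace <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1L]
  m <- regmatches(hdr, regexec("k=(\\d+) m=(\\d+) strand=(\\w+)", hdr))[[1L]]
  if (length(m) != 4L) stop("malformed feature-space header: ", hdr)
  params <- diMismatchParams(as.integer(m[2L]), as.integer(m[3L]), m[4L])
  new("FeatureSpace", features = sort(lines[-1L]), params = params)
}
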