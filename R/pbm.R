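#' Read a PBM probe table
#'
#' Reads a tab-separated table of probes with columns id, sequence and
#' intensity. Sequences are uppercased; duplicated ids and sequences of the
#' wrong length are rejected with messages naming the offending rows.
#'
#' @param path TSV file path.
#' @param probeLength expected probe length (36 for standard PBM designs).
#' @param header whether the file carries a header line.
#' @param designId array-design label; defaults to the file name.
#' @return A \linkS4class{ProbeSet}.
#' @export
readProbeTable <- function(path, probeLength = 36, header = TRUE,
                           designId = basename(path)) {
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3L) stop("probe table needs columns id, sequence, intensity")
  tab <- tab[, 1:3]
  names(tab) <- c("id", "sequence", "intensity")
  tab$sequence <- toupper(tab$sequence)
  bad <- which(nchar(tab$sequence) != probeLength)
  if (length(bad))
    stop("probe sequences with length != ", probeLength, " in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  y <- suppressWarnings(as.numeric(tab$intensity))
  if (anyNA(y))
    stop("non-numeric intensity in row(s): ",
         paste(utils::head(which(is.na(y)), 5L), collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("duplicated probe id(s): ",
         paste(utils::head(unique(tab$id[duplicated(tab$id)]), 5L), collapse = ", "))
  probeSet(tab$id, tab$sequence, y, designId = designId)
}

#' @rdname readProbeTable
#' @param probes a \linkS4class{ProbeSet} to write.
#' @export
writeProbeTable <- function(probes, path) {
  utils::write.table(
    data.frame(id = probes@id, sequence = probes@sequence,
               intensity = probes@intensity, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize probe intensities
#'
#' Robust z-scores of log-intensities: \code{(log y - median) / MAD}, with
#' the usual 1.4826 MAD scaling. The transform is strictly monotone, so probe
#' rankings are preserved. A zero MAD falls back to the scaled IQR and then
#' to 1, so constant inputs normalize to all zeros. Non-positive intensities
#' are shifted above zero with a warning before taking logs.
#'
#' @param probes a \linkS4class{ProbeSet}.
#' @return The same \linkS4class{ProbeSet} with the normalized track filled.
#' @export
normalizeIntensities <- function(probes) {
  if (length(probes) < 2L) stop("need at least 2 probes")
  y <- probes@intensity
  if (any(y <= 0)) {
    warning("non-positive intensities shifted by ", -min(y) + 1,
            " before log transform")
    y <- y - min(y) + 1
  }
  l <- log(y)
  med <- stats::median(l)
  s <- stats::mad(l)
  if (s == 0) s <- stats::IQR(l) / 1.349
  if (s == 0) s <- 1
  probes@normalized <- (l - med) / s
  methods::validObject(probes)
  probes
}

#' Sample an informative training set from a PBM design
#'
#' Positives are the probes whose normalized intensity meets
#' \code{zThreshold}; if fewer than \code{minPositives} qualify, the top
#' \code{minPositives} probes ranked by normalized intensity are taken
#' instead. The same number of negatives is taken from the bottom of the
#' distribution. Ties are broken by probe id so that runs are reproducible.
#'
#' @param probes a normalized \linkS4class{ProbeSet}.
#' @param zThreshold positive cutoff on the robust z scale.
#' @param minPositives minimum (and fallback) number of positives (500 in the
#'   standard protocol).
#' @return A \linkS4class{TrainingSample}; labels are the normalized
#'   intensities, positives first.
#' @export
sampleTrainingProbes <- function(probes, zThreshold = 4, minPositives = 500) {
  z <- probes@normalized
  if (!length(z)) stop("probes must be normalized first (see normalizeIntensities)")
  n <- length(probes)
  nPos <- max(sum(z >= zThreshold), as.integer(minPositives))
  if (2L * nPos > n)
    stop("degenerate sampling: 2 * ", nPos, " positives exceed ", n, " probes")
  ordDesc <- order(-z, probes@id)
  posIdx <- ordDesc[seq_len(nPos)]
  ordAsc <- order(z, probes@id)
  negIdx <- ordAsc[seq_len(nPos)]
  sub <- function(i) new("ProbeSet", id = probes@id[i],
                         sequence = probes@sequence[i],
                         intensity = probes@intensity[i],
                         normalized = z[i], designId = probes@designId)
  new("TrainingSample", positives = sub(posIdx), negatives = sub(negIdx),
      labels = c(z[posIdx], z[negIdx]))
}

# class-mean feature selection shared by SVR and SVM training: rank features
# by |mean feature value among positives - mean among negatives|
.selectByClassMeans <- function(posSeqs, negSeqs, space, maxFeatures) {
  params <- space@params
  if (!length(space@features)) stop("empty feature space")
  mm <- cpp_class_mean_scores(posSeqs, negSeqs, space@features, params@k,
                              minMatchingDinucs(params),
                              params@strandMode == "both")
  d <- abs(mm[1L, ] - mm[2L, ])
  keep <- order(-d, space@features)[seq_len(min(maxFeatures, length(d)))]
  new("FeatureSpace", features = sort(space@features[keep]), params = params)
}

#' Select discriminative k-mer features
#'
#' For each candidate feature, computes the mean di-mismatch feature value
#' over the positive probes and over the negative probes, ranks features by
#' the absolute difference of the two class means (descending, ties broken
#' lexicographically), and keeps at most \code{maxFeatures}.
#'
#' @param sample a \linkS4class{TrainingSample}.
#' @param space candidate \linkS4class{FeatureSpace}.
#' @param maxFeatures cap on the selected set (4000 in the standard
#'   protocol).
#' @return A \linkS4class{FeatureSpace} containing the selected subset.
#' @export
selectFeatures <- function(sample, space, maxFeatures = 4000) {
  .selectByClassMeans(sample@positives@sequence, sample@negatives@sequence,
                      space, as.integer(maxFeatures))
}

#' Serialize a training sample
#'
#' Writes positives and negatives as a pair of FASTA files plus a label TSV
#' (id, class, label).
#'
#' @param sample a \linkS4class{TrainingSample}.
#' @param prefix path prefix; files \code{<prefix>_pos.fa},
#'   \code{<prefix>_neg.fa} and \code{<prefix>_labels.tsv} are written.
#' @export
writeTrainingSample <- function(sample, prefix) {
  pos <- Biostrings::DNAStringSet(stats::setNames(sample@positives@sequence,
                                                  sample@positives@id))
  neg <- Biostrings::DNAStringSet(stats::setNames(sample@negatives@sequence,
                                                  sample@negatives@id))
  Biostrings::writeXStringSet(pos, paste0(prefix, "_pos.fa"))
  Biostrings::writeXStringSet(neg, paste0(prefix, "_neg.fa"))
  utils::write.table(
    data.frame(id = c(sample@positives@id, sample@negatives@id),
               class = rep(c("positive", "negative"),
                           times = c(length(sample@positives@id),
                                     length(sample@negatives@id))),
               label = sample@labels, stringsAsFactors = FALSE),
    paste0(prefix, "_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
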