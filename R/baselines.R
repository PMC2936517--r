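# strand-merged (canonical) contiguous 8-mers per sequence
.canonicalKmerSets <- function(seqs, width) {
  cpp_kmer_sets(seqs, width, TRUE)
}

#' Compute 8-mer enrichment (E-) scores from PBM probes
#'
#' For every strand-merged contiguous 8-mer, measures how enriched the
#' probes containing it are at the top of the intensity ranking, as a
#' rescaled Mann-Whitney rank statistic: AUC(containing vs non-containing)
#' minus 0.5, which lies in [-0.5, 0.5] with values near +0.5 indicating
#' patterns found almost exclusively in bound probes. This is a simplified
#' full-ranking analogue of the published split-half PBM statistic (the
#' array replicate structure needed for the split-half form is not modeled
#' here). 8-mers present in fewer than \code{minSupport} probes are omitted
#' to stabilize the rank statistic.
#'
#' @param probes a \linkS4class{ProbeSet}; normalized intensities are used
#'   when present, raw otherwise.
#' @param minSupport minimum number of containing probes.
#' @param width pattern width (8).
#' @return An \linkS4class{EScoreTable}.
#' @export
computeEscores <- function(probes, minSupport = 20, width = 8) {
  if (!length(probes)) stop("empty probe set")
  y <- if (length(probes@normalized)) probes@normalized else probes@intensity
  sets <- .canonicalKmerSets(probes@sequence, width)
  lens <- lengths(sets)
  kmers <- unlist(sets, use.names = FALSE)
  probeIdx <- rep.int(seq_along(sets), lens)
  r <- rank(y)
  n <- length(y)
  sumR <- rowsum(r[probeIdx], kmers)
  n1 <- rowsum(rep(1, length(kmers)), kmers)
  kmerNames <- rownames(n1)
  n1 <- stats::setNames(as.numeric(n1), kmerNames)
  sumR <- stats::setNames(as.numeric(sumR), kmerNames)
  keep <- n1 >= minSupport & n1 <= n - 1L
  n1 <- n1[keep]
  sumR <- sumR[keep]
  auc <- (sumR - n1 * (n1 + 1) / 2) / (n1 * (n - n1))
  scores <- pmin(pmax(auc - 0.5, -0.5), 0.5)
  new("EScoreTable", scores = scores, width = as.integer(width),
      sourceDesign = probes@designId)
}

#' @describeIn computeEscores the named score vector of a table.
#' @param table an \linkS4class{EScoreTable}.
#' @export
escores <- function(table) table@scores

setMethod("length", "EScoreTable", function(x) length(x@scores))

setMethod("show", "EScoreTable", function(object) {
  cat(sprintf("EScoreTable ('%s'): %d %d-mers, range [%.3f, %.3f]\n",
              object@sourceDesign, length(object@scores), object@width,
              if (length(object@scores)) min(object@scores) else NA,
              if (length(object@scores)) max(object@scores) else NA))
})

#' E-max sequence score
#'
#' Scores each sequence by the maximal E-score over the (strand-merged)
#' 8-mers it contains. With \code{threshold} set (0.35 in the thresholded
#' variant), 8-mers scoring below it are ignored and a sequence containing
#' none yields the -0.5 sentinel; the same sentinel is returned when no
#' contained 8-mer is in the table at all.
#'
#' @param sequences character vector or \code{DNAStringSet} (each >= 8 nt).
#' @param table an \linkS4class{EScoreTable}.
#' @param threshold optional minimal E-score.
#' @return Numeric vector of E-max scores.
#' @export
emaxScore <- function(sequences, table, threshold = NULL) {
  sequences <- .asSeqChar(sequences)
  sets <- .canonicalKmerSets(sequences, table@width)
  vapply(sets, function(km) {
    v <- table@scores[km]
    v <- v[!is.na(v)]
    if (!is.null(threshold)) v <- v[v >= threshold]
    if (!length(v)) -0.5 else max(v)
  }, numeric(1))
}

#' Z-max sequence score
#'
#' Each 8-mer is scored by the median intensity of the training probes that
#' contain it; a sequence's Z-max is the maximum such median over the 8-mers
#' it contains. 8-mers unseen among the training probes are ignored
#' (\code{-Inf} when a sequence contains none).
#'
#' @param sequences character vector or \code{DNAStringSet}.
#' @param probes training \linkS4class{ProbeSet}; normalized intensities are
#'   used when present.
#' @param width pattern width (8).
#' @return Numeric vector of Z-max scores.
#' @export
zmaxScore <- function(sequences, probes, width = 8) {
  y <- if (length(probes@normalized)) probes@normalized else probes@intensity
  sets <- .canonicalKmerSets(probes@sequence, width)
  kmers <- unlist(sets, use.names = FALSE)
  probeIdx <- rep.int(seq_along(sets), lengths(sets))
  med <- tapply(y[probeIdx], kmers, stats::median)
  sequences <- .asSeqChar(sequences)
  qsets <- .canonicalKmerSets(sequences, width)
  vapply(qsets, function(km) {
    v <- med[km]
    v <- v[!is.na(v)]
    if (!length(v)) -Inf else max(v)
  }, numeric(1))
}

#' Construct a PSSM
#'
#' @param probs numeric matrix of per-position base probabilities, width x 4
#'   (columns A, C, G, T); rows off from 1 by more than 1e-6 are an error,
#'   smaller deviations are renormalized.
#' @param background background base probabilities.
#' @param pseudocount added inside the log-odds ratio.
#' @return A \linkS4class{PSSM}.
#' @export
pssm <- function(probs, background = rep(0.25, 4), pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("'probs' must have 4 columns (A, C, G, T)")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6)) stop("PSSM rows must sum to 1")
  probs <- probs / rs
  colnames(probs) <- c("A", "C", "G", "T")
  new("PSSM", probs = probs, background = background,
      pseudocount = pseudocount)
}

#' @describeIn pssm the probability matrix.
#' @param x a \linkS4class{PSSM}.
#' @export
pssmMatrix <- function(x) x@probs

#' @describeIn pssm motif width (number of positions).
#' @export
pssmWidth <- function(x) nrow(x@probs)

setMethod("show", "PSSM", function(object) {
  cons <- paste(c("A", "C", "G", "T")[apply(object@probs, 1L, which.max)],
                collapse = "")
  cat(sprintf("PSSM: width %d, consensus %s\n", nrow(object@probs), cons))
})

#' Build a sharp PSSM from a consensus sequence
#'
#' Probability \code{p} on the consensus base at each position and
#' \code{(1 - p) / 3} elsewhere; the default planted-motif shape of the
#' synthetic generators.
#'
#' @param consensus ACGT string.
#' @param p consensus-base probability.
#' @param pseudocount passed through to \code{\link{pssm}}.
#' @export
consensusPssm <- function(consensus, p = 0.85, pseudocount = 0.01) {
  bases <- strsplit(toupper(consensus), "")[[1L]]
  idx <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(idx)) stop("consensus must be an ACGT string")
  mat <- matrix((1 - p) / 3, nrow = length(idx), ncol = 4L)
  mat[cbind(seq_along(idx), idx)] <- p
  pssm(mat, pseudocount = pseudocount)
}

# log-odds matrix with pseudocount folded in; uniform rows stay exactly 0
.pssmLogOdds <- function(x) {
  p <- (x@probs + x@pseudocount) / (1 + 4 * x@pseudocount)
  log(sweep(p, 2L, x@background, "/"))
}

.reverseComplementPssm <- function(x) {
  new("PSSM", probs = x@probs[rev(seq_len(nrow(x@probs))), c(4L, 3L, 2L, 1L),
                              drop = FALSE],
      background = x@background[c(4L, 3L, 2L, 1L)],
      pseudocount = x@pseudocount)
}

# per-window max-over-strands log-odds for each sequence:
# a list with matrix [seq, offset]
.pssmWindowScores <- function(x, seqs, bothStrands = TRUE) {
  w <- nrow(x@probs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must have equal length")
  if (L < w) stop("PSSM wider than the sequences")
  lo <- .pssmLogOdds(x)
  lorc <- .pssmLogOdds(.reverseComplementPssm(x))
  codes <- matrix(match(unlist(strsplit(seqs, ""), use.names = FALSE),
                        c("A", "C", "G", "T")),
                  nrow = length(seqs), byrow = TRUE)
  nOff <- L - w + 1L
  out <- matrix(0, nrow = length(seqs), ncol = nOff)
  for (off in seq_len(nOff)) {
    sFwd <- numeric(length(seqs))
    sRev <- numeric(length(seqs))
    for (j in seq_len(w)) {
      cj <- codes[, off + j - 1L]
      ok <- !is.na(cj)
      # windows with ambiguous bases get -Inf on both strands
      sFwd[!ok] <- -Inf
      sRev[!ok] <- -Inf
      sFwd[ok] <- sFwd[ok] + lo[cbind(j, cj[ok])]
      sRev[ok] <- sRev[ok] + lorc[cbind(j, cj[ok])]
    }
    out[, off] <- if (bothStrands) pmax(sFwd, sRev) else sFwd
  }
  out
}

#' Maximum PSSM log-odds score of a sequence
#'
#' The maximum, over all windows and both strands, of the summed per-position
#' log-odds \code{log(p[pos, base] / background[base])} (with pseudocount).
#' Used to score intergenic regions with PBM-derived PSSMs.
#'
#' @param x a \linkS4class{PSSM}.
#' @param sequences character vector or \code{DNAStringSet}, each at least
#'   as long as the motif.
#' @return Numeric vector of maximal log-odds scores.
#' @export
pssmLogOddsMax <- function(x, sequences) {
  sequences <- .asSeqChar(sequences)
  w <- nrow(x@probs)
  if (any(nchar(sequences) < w)) stop("sequence shorter than the PSSM width")
  lo <- .pssmLogOdds(x)
  lorc <- .pssmLogOdds(.reverseComplementPssm(x))
  vapply(sequences, function(s) {
    bases <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
    best <- -Inf
    for (off in seq_len(length(bases) - w + 1L)) {
      idx <- bases[off:(off + w - 1L)]
      if (anyNA(idx)) next
      best <- max(best, sum(lo[cbind(seq_len(w), idx)]),
                  sum(lorc[cbind(seq_len(w), idx)]))
    }
    best
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read / write a PSSM in minimal MEME format
#'
#' Supports the letter-probability matrix block of MEME motif files
#' (alphabet ACGT). Probabilities off from 1 by more than 1e-6 per position
#' are renormalized with a warning.
#'
#' @param path file path.
#' @param x a \linkS4class{PSSM} (for writing).
#' @param name motif name written to the MOTIF line.
#' @return \code{readPSSM} returns a \linkS4class{PSSM}.
#' @export
readPSSM <- function(path) {
  lines <- readLines(path)
  bgLine <- grep("^Background letter frequencies", lines)
  background <- rep(0.25, 4)
  if (length(bgLine)) {
    toks <- strsplit(trimws(lines[bgLine[1L] + 1L]), "\\s+")[[1L]]
    background <- as.numeric(toks[seq(2L, 8L, by = 2L)])
  }
  hdr <- grep("letter-probability matrix", lines)
  if (!length(hdr)) stop("no letter-probability matrix block found")
  hline <- lines[hdr[1L]]
  wTok <- regmatches(hline, regexec("w=\\s*(\\d+)", hline))[[1L]]
  if (length(wTok) < 2L) stop("malformed matrix header: ", hline)
  w <- as.integer(wTok[2L])
  if (w < 1L) stop("PSSM width must be >= 1")
  rows <- lines[(hdr[1L] + 1L):(hdr[1L] + w)]
  mat <- t(vapply(rows, function(r)
    as.numeric(strsplit(trimws(r), "\\s+")[[1L]][1:4]), numeric(4),
    USE.NAMES = FALSE))
  dimnames(mat) <- NULL
  if (anyNA(mat)) stop("malformed probability row in ", path)
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-6)) {
    warning("PSSM rows renormalized (off from 1 by up to ",
            format(max(abs(rs - 1))), ")")
    mat <- mat / rs
  }
  pssm(mat / rowSums(mat), background = background)
}

#' @rdname readPSSM
#' @export
writePSSM <- function(x, path, name = "motif") {
  bg <- x@background
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "Background letter frequencies",
             sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
             "", paste("MOTIF", name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 50 E= 0",
                     nrow(x@probs)),
             apply(x@probs, 1L, function(r)
               sprintf(" %.8f %.8f %.8f %.8f", r[1], r[2], r[3], r[4])))
  writeLines(lines, path)
  invisible(path)
}
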