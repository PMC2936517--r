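#' Extract balanced 60-bp training windows from ChIP peaks
#'
#' For each of the top \code{nPeaks} peaks (by score), the positive example
#' is the 60-bp window centered on the summit
#' (\code{[summit - 30, summit + 30)}) and the negative example is the 60-bp
#' window whose center lies \code{shift} bp (300 by default) to the left of
#' the summit. Peaks whose windows would run off the chromosome or contain
#' more than 50% ambiguous bases are skipped with a message, keeping the
#' output balanced.
#'
#' @param peaks a \linkS4class{PeakSet}.
#' @param genome named \code{DNAStringSet} (or named character) covering all
#'   peak chromosomes.
#' @param nPeaks number of top peaks to use (1000 in the standard protocol).
#' @param windowSize window width in bp.
#' @param shift distance from summit to the negative-window center; positive
#'   values shift leftward.
#' @return A \linkS4class{LabeledWindowSet} (positives then negatives).
#' @export
extractTrainingWindows <- function(peaks, genome, nPeaks = 1000,
                                   windowSize = 60, shift = 300) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(peaks@chrom), names(genome))
  if (length(missing))
    stop("peak chromosome(s) absent from the genome: ",
         paste(missing, collapse = ", "))
  ord <- order(-peaks@score, peaks@chrom, peaks@summit)
  ord <- ord[seq_len(min(nPeaks, length(ord)))]
  half <- windowSize %/% 2L
  chrLen <- stats::setNames(Biostrings::width(genome), names(genome))
  posSeq <- negSeq <- posOrig <- negOrig <- character(0)
  skipped <- 0L
  for (i in ord) {
    chrom <- peaks@chrom[i]
    s <- peaks@summit[i]
    pStart <- s - half                  # 0-based half-open
    nStart <- s - shift - half
    if (pStart < 0L || nStart < 0L ||
        pStart + windowSize > chrLen[chrom] ||
        nStart + windowSize > chrLen[chrom]) {
      skipped <- skipped + 1L
      next
    }
    pw <- as.character(Biostrings::subseq(genome[[chrom]], pStart + 1L,
                                          pStart + windowSize))
    nw <- as.character(Biostrings::subseq(genome[[chrom]], nStart + 1L,
                                          nStart + windowSize))
    nFrac <- function(x) 1 - sum(strsplit(x, "")[[1L]] %in%
                                   c("A", "C", "G", "T")) / nchar(x)
    if (nFrac(pw) > 0.5 || nFrac(nw) > 0.5) {
      skipped <- skipped + 1L
      next
    }
    posSeq <- c(posSeq, pw)
    negSeq <- c(negSeq, nw)
    posOrig <- c(posOrig, sprintf("%s:%d-%d", chrom, pStart, pStart + windowSize))
    negOrig <- c(negOrig, sprintf("%s:%d-%d", chrom, nStart, nStart + windowSize))
  }
  if (skipped)
    message(skipped, " peak(s) skipped (off-chromosome or N-heavy windows)")
  if (length(posSeq) < 10L)
    stop("fewer than 10 usable peaks after filtering")
  labeledWindowSet(c(posSeq, negSeq),
                   rep(c(1L, -1L), times = c(length(posSeq), length(negSeq))),
                   c(posOrig, negOrig))
}

#' Read a peak list from a BED-like file
#'
#' Columns: chrom, start, end, then optionally name, score and a summit
#' offset column (position of the summit relative to the interval start).
#' Without a summit column the interval midpoint is used.
#'
#' @param path file path.
#' @param header whether the file carries a header line.
#' @return A \linkS4class{PeakSet}.
#' @export
readPeaksBed <- function(path, header = FALSE) {
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("peak file needs at least chrom, start, end")
  chrom <- as.character(tab[[1L]])
  start <- as.integer(tab[[2L]])
  end <- as.integer(tab[[3L]])
  score <- if (ncol(tab) >= 5L) as.numeric(tab[[5L]]) else rev(seq_along(chrom))
  summit <- if (ncol(tab) >= 6L) start + as.integer(tab[[6L]])
            else (start + end) %/% 2L
  peakSet(chrom, summit, score)
}

#' Train and cross-validate the in vivo SVM
#'
#' Delegates to \code{\link{crossvalAUC}} for the 10-fold cross-validated
#' AUC and to \code{\link{trainClassifier}} for the final model trained on
#' all windows.
#'
#' @param windows a \linkS4class{LabeledWindowSet}.
#' @param config \linkS4class{TrainingConfig} (classification).
#' @param folds,seed cross-validation folds and seed.
#' @return List with the final \code{model}, the \code{meanAUC} and the
#'   per-fold AUCs.
#' @export
runChipTraining <- function(windows,
                            config = trainingConfig(mode = "classification"),
                            folds = 10, seed = 1) {
  cv <- crossvalAUC(windows, config, folds = folds, seed = seed)
  model <- trainClassifier(windows, config)
  list(model = model, meanAUC = cv$mean, perFold = cv$perFold)
}

#' Compare models on a fixed ChIP window set
#'
#' Scores every window with each model - classification models by their
#' decision value on the full window, regression (PBM-derived) models by
#' their maximum 36-mer window score - and reports one ROC AUC per model.
#'
#' @param windows a \linkS4class{LabeledWindowSet}.
#' @param models named list of \linkS4class{LinearSequenceModel}s.
#' @param windowLength scanning window for regression models.
#' @return A data.frame (model, auc) sorted by decreasing AUC.
#' @export
compareModels <- function(windows, models, windowLength = 36) {
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("'models' must be a named list")
  seqs <- windows@sequences
  aucs <- vapply(models, function(m) {
    scores <- if (m@config@mode == "classification")
      predictScores(m, seqs)
    else
      vapply(seqs, function(s) maxWindowScore(m, s, windowLength),
             numeric(1), USE.NAMES = FALSE)
    .rocAuc(windows@labels, scores)
  }, numeric(1))
  out <- data.frame(model = names(models), auc = as.numeric(aucs),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$auc, out$model), , drop = FALSE]
}

#' Write labeled windows as FASTA
#'
#' Headers carry the window origin and label
#' (\code{><origin> label=<+1/-1>}).
#'
#' @param windows a \linkS4class{LabeledWindowSet}.
#' @param path output FASTA.
#' @export
writeWindowsFasta <- function(windows, path) {
  ids <- sprintf("%s label=%+d",
                 ifelse(nzchar(windows@origin), windows@origin,
                        paste0("window", seq_along(windows@sequences))),
                 windows@labels)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(windows@sequences, ids)), path)
  invisible(path)
}
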