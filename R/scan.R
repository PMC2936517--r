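#' Scan a region with a trained model
#'
#' Slides a fixed-length window (36 nt by default, matching PBM probe
#' length) along the region and scores each window with the model. Scores
#' are computed through the k-mer contribution table, so the cost is linear
#' in region length; windows consisting entirely of ambiguous bases score
#' the model bias.
#'
#' @param model a \linkS4class{LinearSequenceModel}.
#' @param sequence region sequence (character or \code{DNAString}), at least
#'   \code{windowLength} long.
#' @param windowLength scoring window (>= model k).
#' @param stride step between window starts.
#' @param regionId identifier carried into the profile.
#' @param regionStart 0-based genomic start (only used for bedGraph export).
#' @return A \linkS4class{BindingProfile}.
#' @export
scanSequence <- function(model, sequence, windowLength = 36, stride = 1,
                         regionId = "region", regionStart = 0) {
  sequence <- .asSeqChar(sequence)[1L]
  params <- model@config@params
  windowLength <- as.integer(windowLength)
  if (windowLength < params@k) stop("'windowLength' must be >= model k")
  L <- nchar(sequence)
  if (L < windowLength) stop("region shorter than the scoring window")
  contribs <- cpp_position_contribs(sequence, model@space@features,
                                    model@weights, params@k,
                                    minMatchingDinucs(params),
                                    params@strandMode == "both")
  cs <- c(0, cumsum(contribs))
  nPerWin <- windowLength - params@k + 1L
  starts <- seq.int(1L, L - windowLength + 1L, by = stride)
  scores <- model@bias + cs[starts + nPerWin] - cs[starts]
  new("BindingProfile", regionId = regionId, scores = as.numeric(scores),
      windowLength = windowLength, stride = as.integer(stride),
      regionStart = as.integer(regionStart))
}

#' @describeIn scanSequence the per-window scores of a profile.
#' @param profile a \linkS4class{BindingProfile}.
#' @export
windowScores <- function(profile) profile@scores

setMethod("show", "BindingProfile", function(object) {
  cat(sprintf("BindingProfile '%s': %d windows of %d nt (stride %d), max %.4g\n",
              object@regionId, length(object@scores), object@windowLength,
              object@stride, max(object@scores)))
})

#' Maximum sliding-window score of a sequence
#'
#' The height of the best-scoring window; used to rank intergenic regions
#' and to score 60-bp ChIP windows with a PBM-derived model (a 60-nt
#' sequence yields 25 windows of 36 nt).
#'
#' @inheritParams scanSequence
#' @return A single numeric score.
#' @export
maxWindowScore <- function(model, sequence, windowLength = 36) {
  max(scanSequence(model, sequence, windowLength)@scores)
}

#' Rank regions by their best window
#'
#' Scores each region by the maximum of its sliding-window profile and
#' returns regions in decreasing score order (ties broken by region id), the
#' ranking used for intergenic-region occupancy prediction.
#'
#' @param model a \linkS4class{LinearSequenceModel}.
#' @param regions named character vector or \code{DNAStringSet} of region
#'   sequences.
#' @param windowLength scoring window length.
#' @return A data.frame with columns \code{regionId} and \code{maxScore}.
#' @export
rankRegions <- function(model, regions, windowLength = 36) {
  seqs <- .asSeqChar(regions)
  ids <- names(regions)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  scores <- vapply(seqs, function(s)
    maxWindowScore(model, s, windowLength), numeric(1), USE.NAMES = FALSE)
  ord <- order(-scores, ids)
  data.frame(regionId = ids[ord], maxScore = scores[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Extract region sequences from a genome FASTA and a BED file
#'
#' BED coordinates are 0-based half-open; FASTA sequence names must match
#' the BED chromosome names (the first whitespace-separated word of each
#' FASTA header is used).
#'
#' @param bedPath BED file of regions.
#' @param fastaPath genome FASTA.
#' @return A named \code{DNAStringSet}; names come from the BED name column
#'   when present, otherwise \code{chrom:start-end}.
#' @export
regionsFromBed <- function(bedPath, fastaPath) {
  gr <- rtracklayer::import(bedPath, format = "BED")
  genome <- Biostrings::readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chroms <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(chroms), names(genome))
  if (length(missing))
    stop("BED chromosome(s) absent from the FASTA: ",
         paste(missing, collapse = ", "))
  starts <- BiocGenerics::start(gr)  # 1-based after import
  ends <- BiocGenerics::end(gr)
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i)
    as.character(Biostrings::subseq(genome[[chroms[i]]], starts[i], ends[i])),
    character(1)))
  ids <- gr$name
  if (is.null(ids) || anyNA(ids))
    ids <- sprintf("%s:%d-%d", chroms, starts - 1L, ends)
  names(seqs) <- ids
  seqs
}

#' Write a binding profile as bedGraph
#'
#' One line per scoring window: chrom, window start, window end (0-based
#' half-open) and the model score.
#'
#' @param profile a \linkS4class{BindingProfile}.
#' @param chrom chromosome name of the scanned region.
#' @param path output file.
#' @export
writeBindingProfile <- function(profile, chrom, path) {
  starts <- profile@regionStart +
    seq.int(0L, by = profile@stride, length.out = length(profile@scores))
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = starts + 1L,
                            width = profile@windowLength),
    score = profile@scores)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
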