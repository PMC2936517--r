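#' Specify a synthetic PBM / ChIP experiment
#'
#' The generator plants sites sampled from known PSSMs into otherwise
#' uniform-random sequence and produces intensities through an additive
#' site-energy model: the log-intensity of a probe is the sum over its
#' windows of a softplus-transformed PSSM log-odds, scaled by the effect
#' size, plus Gaussian noise. All outputs are fully reproducible from the
#' seed.
#'
#' @param seed integer seed.
#' @param nProbes probes per array design (standard PBM designs carry
#'   ~40K probes).
#' @param probeLength probe length (36).
#' @param plantedPssms list of \linkS4class{PSSM}s; planted probes are
#'   assigned one of them at random.
#' @param effectSizes per-PSSM multiplier on the softplus site energy.
#' @param noiseSd Gaussian noise SD on the log-intensity scale.
#' @param chemicalPotential offset subtracted from each window's PSSM
#'   log-odds before the softplus. With the default sharp 8-mer PSSM, 5 sits
#'   between the log-odds of a 6/8 and a 7/8 consensus match, so windows
#'   below a near-perfect site are effectively unbound and, as in real PBM
#'   experiments, only a few hundred probes per design show binding.
#' @param plantFraction fraction of probes receiving a planted site.
#' @param genomeLength,nPeaks ChIP-side dimensions; peaks are spaced at
#'   least 600 bp apart so positive and negative windows never collide.
#' @param cofactor optional \linkS4class{PSSM} planted in a fraction of
#'   positive ChIP windows.
#' @param cofactorFraction fraction of positives carrying the cofactor site.
#' @param cofactorMode \code{"beside"} (both sites) or \code{"instead"}
#'   (cofactor replaces the primary site).
#' @return A \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(seed = 1, nProbes = 40000, probeLength = 36,
                          plantedPssms = list(consensusPssm("ATGCAAAT")),
                          effectSizes = rep(2, length(plantedPssms)),
                          noiseSd = 0.5, chemicalPotential = 5,
                          plantFraction = 0.05,
                          genomeLength = 1e6, nPeaks = 1000,
                          cofactor = NULL, cofactorFraction = 0,
                          cofactorMode = c("beside", "instead")) {
  cofactorMode <- match.arg(cofactorMode)
  new("SyntheticSpec", seed = as.integer(seed), nProbes = as.integer(nProbes),
      probeLength = as.integer(probeLength), plantedPssms = plantedPssms,
      effectSizes = as.numeric(effectSizes), noiseSd = as.numeric(noiseSd),
      chemicalPotential = as.numeric(chemicalPotential),
      plantFraction = as.numeric(plantFraction),
      genomeLength = as.integer(genomeLength), nPeaks = as.integer(nPeaks),
      cofactor = if (is.null(cofactor)) list() else list(cofactor),
      cofactorFraction = as.numeric(cofactorFraction),
      cofactorMode = cofactorMode)
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: seed %d, %d probes x %d nt, %d planted PSSM(s), ",
                     "plant fraction %.3g, noise SD %.3g\n"),
              object@seed, object@nProbes, object@probeLength,
              length(object@plantedPssms), object@plantFraction,
              object@noiseSd))
})

.randomSeqs <- function(n, L) {
  mat <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE),
                nrow = n)
  apply(mat, 1L, paste, collapse = "")
}

# draw a site from the PSSM; when mu is given, condition on the site being
# bound (rejection sampling with acceptance = occupancy sigma(logodds - mu)),
# the affinity-weighted distribution appropriate for sites under observed
# binding events such as confident ChIP peaks
.sampleSite <- function(x, mu = NULL) {
  probs <- x@probs
  lo <- .pssmLogOdds(x)
  repeat {
    idx <- vapply(seq_len(nrow(probs)), function(j)
      sample.int(4L, 1L, prob = probs[j, ]), integer(1))
    if (is.null(mu)) break
    siteLo <- sum(lo[cbind(seq_along(idx), idx)])
    if (stats::runif(1) < stats::plogis(siteLo - mu)) break
  }
  paste(c("A", "C", "G", "T")[idx], collapse = "")
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# additive site energy of each probe under one planted PSSM: per-window
# occupancy-like softplus of (log-odds - chemical potential), summed
.probeEnergy <- function(x, seqs, mu = 5) {
  rowSums(.softplus(.pssmWindowScores(x, seqs, bothStrands = TRUE) - mu))
}

.simulateDesign <- function(spec, designId) {
  n <- spec@nProbes
  L <- spec@probeLength
  seqs <- .randomSeqs(n, L)
  nPlant <- floor(spec@plantFraction * n)
  plantIdx <- sample.int(n, nPlant)
  whichPssm <- sample.int(length(spec@plantedPssms), nPlant, replace = TRUE)
  for (t in seq_len(nPlant)) {
    x <- spec@plantedPssms[[whichPssm[t]]]
    w <- nrow(x@probs)
    if (w > L) stop("planted motif wider than the probe")
    site <- .sampleSite(x)
    if (sample(c(TRUE, FALSE), 1L)) site <- as.character(cpp_revcomp(site))
    off <- sample.int(L - w + 1L, 1L)
    substr(seqs[plantIdx[t]], off, off + w - 1L) <- site
  }
  logI <- stats::rnorm(n, sd = spec@noiseSd)
  for (j in seq_along(spec@plantedPssms))
    logI <- logI + spec@effectSizes[j] *
      .probeEnergy(spec@plantedPssms[[j]], seqs, spec@chemicalPotential)
  ps <- probeSet(sprintf("%s_%06d", designId, seq_len(n)), seqs, exp(logI),
                 designId = designId)
  attr(ps, "plantedIdx") <- plantIdx
  ps
}

#' Simulate a pair of PBM array designs
#'
#' Generates two disjoint probe designs under the same planted-motif
#' intensity model, emulating the cross-design train/test setting of real
#' PBM experiments (two independent probe sets measured for the same TF).
#' Disjointness of the probe sequences is enforced by regenerating any
#' collisions.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return List with \code{designA} and \code{designB}
#'   (\linkS4class{ProbeSet}s); each carries the planted probe indices in
#'   attribute \code{"plantedIdx"}.
#' @export
simulatePBMExperiment <- function(spec) {
  set.seed(spec@seed)
  a <- .simulateDesign(spec, "designA")
  b <- .simulateDesign(spec, "designB")
  dup <- which(b@sequence %in% a@sequence)
  while (length(dup)) {
    b@sequence[dup] <- .randomSeqs(length(dup), spec@probeLength)
    dup <- which(b@sequence %in% a@sequence)
  }
  list(designA = a, designB = b)
}

#' Simulate a ChIP-like experiment with planted motifs
#'
#' Generates a random genome, places non-overlapping peak summits (pairwise
#' distance at least 600 bp), plants a site sampled from the primary PSSM in
#' each positive window and optionally a cofactor site in a fraction of
#' positives, then derives the balanced 60-bp window set with
#' \code{\link{extractTrainingWindows}} so windows, peaks and genome are
#' mutually consistent. Negative windows receive no planted site.
#'
#' @param spec a \linkS4class{SyntheticSpec}; the first element of
#'   \code{plantedPssms} is the primary in vivo motif.
#' @return List with \code{genome} (named \code{DNAStringSet}),
#'   \code{peaks} (\linkS4class{PeakSet}), \code{windows}
#'   (\linkS4class{LabeledWindowSet}) and \code{sites} (data.frame of
#'   planted site positions and sequences).
#' @export
simulateChipExperiment <- function(spec) {
  set.seed(spec@seed)
  G <- spec@genomeLength
  n <- spec@nPeaks
  if (G <= 600L * n)
    stop("overlap constraint unsatisfiable: genomeLength must exceed 600 * nPeaks")
  step <- (G - 800L) %/% n
  jitter <- sample.int(step - 600L + 1L, n, replace = TRUE) - 1L
  summits <- 400L + (seq_len(n) - 1L) * step + jitter
  genomeSeq <- paste(sample(c("A", "C", "G", "T"), G, replace = TRUE),
                     collapse = "")
  primary <- spec@plantedPssms[[1L]]
  wP <- nrow(primary@probs)
  cof <- if (length(spec@cofactor)) spec@cofactor[[1L]] else NULL
  useCof <- if (!is.null(cof))
    stats::runif(n) < spec@cofactorFraction else rep(FALSE, n)
  sites <- list()
  plant <- function(x, lo, hi) {
    # plant a bound (affinity-conditioned) site fully inside [lo, hi)
    # (0-based genome coordinates)
    w <- nrow(x@probs)
    site <- .sampleSite(x, mu = spec@chemicalPotential)
    if (sample(c(TRUE, FALSE), 1L)) site <- as.character(cpp_revcomp(site))
    off <- lo + sample.int(hi - lo - w + 1L, 1L) - 1L
    substr(genomeSeq, off + 1L, off + w) <<- site
    data.frame(start = off, end = off + w, site = site,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    s <- summits[i]
    if (useCof[i] && spec@cofactorMode == "instead") {
      sites[[length(sites) + 1L]] <- cbind(plant(cof, s - 30L, s + 30L),
                                           motif = "cofactor", peak = i)
    } else {
      # primary site in the left half, cofactor (if any) in the right half
      sites[[length(sites) + 1L]] <- cbind(plant(primary, s - 30L, s),
                                           motif = "primary", peak = i)
      if (useCof[i])
        sites[[length(sites) + 1L]] <- cbind(plant(cof, s, s + 30L),
                                             motif = "cofactor", peak = i)
    }
  }
  genome <- Biostrings::DNAStringSet(c(chrSim = genomeSeq))
  peaks <- peakSet(rep("chrSim", n), summits, score = rev(seq_len(n)))
  windows <- extractTrainingWindows(peaks, genome, nPeaks = n)
  list(genome = genome, peaks = peaks, windows = windows,
       sites = do.call(rbind, sites))
}
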