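# Naive reference implementations, kept deliberately independent of the
# package's C++ fast paths: plain string splitting and double loops.

oracleRevcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# raw matching-dinucleotide count between two k-mers
oracleRawMatches <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  k <- length(ca)
  sum(vapply(seq_len(k - 1L), function(i)
    ca[i] == cb[i] && ca[i + 1L] == cb[i + 1L], logical(1)))
}

oracleDiScore <- function(a, b, k, m, both = FALSE) {
  minMatch <- k - 1L - m
  s <- oracleRawMatches(a, b)
  if (both) s <- max(s, oracleRawMatches(a, oracleRevcomp(b)))
  if (s < minMatch) 0L else s
}

oracleWindows <- function(seq, k) {
  L <- nchar(seq)
  vapply(seq_len(L - k + 1L), function(i) substr(seq, i, i + k - 1L),
         character(1))
}

oracleFeatureMap <- function(seqs, feats, k, m, both = FALSE) {
  t(vapply(seqs, function(s) {
    wins <- oracleWindows(s, k)
    wins <- wins[!grepl("[^ACGT]", wins)]
    vapply(feats, function(f)
      sum(vapply(wins, oracleDiScore, numeric(1), b = f, k = k, m = m,
                 both = both)),
      numeric(1))
  }, numeric(length(feats))))
}

oraclePredict <- function(seq, feats, w, bias, k, m, both = FALSE) {
  fm <- oracleFeatureMap(seq, feats, k, m, both)
  as.numeric(fm %*% w) + bias
}

randomDNA <- function(n, L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

# Rand index between two 2-cluster labelings, closed form
randIndex <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  (choose(n, 2) + sum(tab^2) -
     0.5 * (sum(rowSums(tab)^2) + sum(colSums(tab)^2))) / choose(n, 2)
}

# plant a literal site into a random host sequence at a random offset
plantSite <- function(host, site, offset = NULL) {
  w <- nchar(site)
  if (is.null(offset)) offset <- sample.int(nchar(host) - w + 1L, 1L)
  substr(host, offset, offset + w - 1L) <- site
  host
}
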