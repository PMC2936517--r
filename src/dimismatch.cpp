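#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <string>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Di-mismatch kernel core. A k-mer is encoded by its k-1 overlapping
// dinucleotides, each a 4-bit code, packed into one 64-bit word (hence the
// k <= 16 limit enforced at the R level). The di-mismatch score between two
// k-mers is the number of equal nibbles, computed with a SWAR zero-nibble
// count on the XOR of the packed words.

static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char compBase(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

static std::string revComp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = compBase(r[i]);
  return r;
}

// pack the k-1 dinucleotide codes of s[0..k-1]; false if any non-ACGT base
static bool packKmer(const char* s, int k, uint64_t* out) {
  uint64_t p = 0;
  int prev = baseCode(s[0]);
  if (prev < 0) return false;
  for (int i = 1; i < k; ++i) {
    int b = baseCode(s[i]);
    if (b < 0) return false;
    p |= ((uint64_t)(prev * 4 + b)) << (4 * (i - 1));
    prev = b;
  }
  *out = p;
  return true;
}

static inline uint64_t nibbleMask(int n) {
  uint64_t m = 0;
  for (int i = 0; i < n; ++i) m |= ((uint64_t)1) << (4 * i);
  return m;
}

// number of equal dinucleotides between two packed k-mers
static inline int rawMatches(uint64_t a, uint64_t b, int km1, uint64_t mask) {
  uint64_t x = a ^ b;
  uint64_t t = (x | (x >> 1) | (x >> 2) | (x >> 3)) & mask;
  return km1 - __builtin_popcountll(t);
}

static void packFeatures(const CharacterVector& feats, int k, bool both,
                         std::vector<uint64_t>& f1, std::vector<uint64_t>& f2) {
  int n = feats.size();
  f1.resize(n);
  f2.resize(both ? n : 0);
  for (int j = 0; j < n; ++j) {
    std::string f = as<std::string>(feats[j]);
    if ((int)f.size() != k)
      stop("feature '" + f + "' does not have length k");
    if (!packKmer(f.c_str(), k, &f1[j]))
      stop("feature '" + f + "' contains a non-ACGT character");
    if (both) packKmer(revComp(f).c_str(), k, &f2[j]);
  }
}

// valid (all-ACGT) windows of a sequence, packed; invalid windows dropped
static void packWindows(const std::string& s, int k, std::vector<uint64_t>& out) {
  out.clear();
  int L = (int)s.size();
  if (L < k) return;
  for (int i = 0; i + k <= L; ++i) {
    uint64_t p;
    if (packKmer(s.c_str() + i, k, &p)) out.push_back(p);
  }
}

static inline int scorePacked(uint64_t w, uint64_t f1, uint64_t f2, bool both,
                              int km1, uint64_t mask, int minMatch) {
  int s = rawMatches(w, f1, km1, mask);
  if (both) {
    int s2 = rawMatches(w, f2, km1, mask);
    if (s2 > s) s = s2;
  }
  return (s < minMatch) ? 0 : s;
}

// [[Rcpp::export]]
IntegerVector cpp_score_pairs(CharacterVector a, CharacterVector b, int k,
                              int minMatch, bool both) {
  if (a.size() != b.size()) stop("'a' and 'b' must have equal length");
  int n = a.size(), km1 = k - 1;
  uint64_t mask = nibbleMask(km1);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i]);
    std::string sb = as<std::string>(b[i]);
    uint64_t pa, pb, pb2 = 0;
    if ((int)sa.size() != k || !packKmer(sa.c_str(), k, &pa))
      stop("invalid k-mer '" + sa + "'");
    if ((int)sb.size() != k || !packKmer(sb.c_str(), k, &pb))
      stop("invalid k-mer '" + sb + "'");
    if (both) packKmer(revComp(sb).c_str(), k, &pb2);
    out[i] = scorePacked(pa, pb, pb2, both, km1, mask, minMatch);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_feature_map(CharacterVector seqs, CharacterVector feats,
                              int k, int minMatch, bool both) {
  int ns = seqs.size(), nf = feats.size(), km1 = k - 1;
  uint64_t mask = nibbleMask(km1);
  std::vector<uint64_t> f1, f2;
  packFeatures(feats, k, both, f1, f2);
  NumericMatrix out(ns, nf);
  std::vector<uint64_t> win;
  for (int i = 0; i < ns; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) stop("sequence shorter than k");
    packWindows(s, k, win);
    for (int j = 0; j < nf; ++j) {
      double acc = 0.0;
      uint64_t a = f1[j], b = both ? f2[j] : 0;
      for (size_t t = 0; t < win.size(); ++t)
        acc += scorePacked(win[t], a, b, both, km1, mask, minMatch);
      out(i, j) = acc;
    }
  }
  return out;
}

// column means of the feature map over two probe classes, without
// materialising the per-probe matrix (row 1 = positives, row 2 = negatives)
// [[Rcpp::export]]
NumericMatrix cpp_class_mean_scores(CharacterVector pos, CharacterVector neg,
                                    CharacterVector feats, int k, int minMatch,
                                    bool both) {
  int nf = feats.size(), km1 = k - 1;
  uint64_t mask = nibbleMask(km1);
  std::vector<uint64_t> f1, f2;
  packFeatures(feats, k, both, f1, f2);
  NumericMatrix out(2, nf);
  std::vector<uint64_t> win;
  for (int cls = 0; cls < 2; ++cls) {
    const CharacterVector& ss = (cls == 0) ? pos : neg;
    int ns = ss.size();
    if (ns == 0) stop("empty probe class");
    for (int i = 0; i < ns; ++i) {
      std::string s = as<std::string>(ss[i]);
      if ((int)s.size() < k) stop("sequence shorter than k");
      packWindows(s, k, win);
      for (int j = 0; j < nf; ++j) {
        double acc = 0.0;
        uint64_t a = f1[j], b = both ? f2[j] : 0;
        for (size_t t = 0; t < win.size(); ++t)
          acc += scorePacked(win[t], a, b, both, km1, mask, minMatch);
        out(cls, j) += acc;
      }
    }
    for (int j = 0; j < nf; ++j) out(cls, j) /= ns;
  }
  return out;
}

// per-group sums of feature-map values: row g = sum over sequences in group
// g of their feature vectors. Lets cross-validation recover every fold's
// class means from one pairwise pass (train-fold sum = total - held-out).
// [[Rcpp::export]]
NumericMatrix cpp_group_sum_scores(CharacterVector seqs, IntegerVector group,
                                   int nGroups, CharacterVector feats, int k,
                                   int minMatch, bool both) {
  int ns = seqs.size(), nf = feats.size(), km1 = k - 1;
  if (group.size() != ns) stop("one group index per sequence is required");
  uint64_t mask = nibbleMask(km1);
  std::vector<uint64_t> f1, f2;
  packFeatures(feats, k, both, f1, f2);
  NumericMatrix out(nGroups, nf);
  std::vector<uint64_t> win;
  for (int i = 0; i < ns; ++i) {
    int g = group[i];
    if (g < 0 || g >= nGroups) stop("group index out of range");
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) stop("sequence shorter than k");
    packWindows(s, k, win);
    const uint64_t* fw = f1.data();
    const uint64_t* fr = both ? f2.data() : f1.data();
    for (int j = 0; j < nf; ++j) {
      double acc = 0.0;
      uint64_t a = fw[j], b = fr[j];
      for (size_t t = 0; t < win.size(); ++t) {
        int sc = rawMatches(win[t], a, km1, mask);
        if (both) {
          int s2 = rawMatches(win[t], b, km1, mask);
          if (s2 > sc) sc = s2;
        }
        if (sc >= minMatch) acc += sc;
      }
      out(g, j) += acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_unique_kmers(CharacterVector seqs, int k, bool canonical) {
  std::set<std::string> acc;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = (int)s.size();
    for (int p = 0; p + k <= L; ++p) {
      std::string w = s.substr(p, k);
      bool ok = true;
      for (int q = 0; q < k; ++q)
        if (baseCode(w[q]) < 0) { ok = false; break; }
      if (!ok) continue;
      for (int q = 0; q < k; ++q) w[q] = toupper(w[q]);
      if (canonical) {
        std::string rc = revComp(w);
        if (rc < w) w = rc;
      }
      acc.insert(w);
    }
  }
  return wrap(std::vector<std::string>(acc.begin(), acc.end()));
}

// per-seq sets of k-mers (canonicalised if requested), as a list
// [[Rcpp::export]]
List cpp_kmer_sets(CharacterVector seqs, int k, bool canonical) {
  List out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    CharacterVector one(1);
    one[0] = seqs[i];
    out[i] = cpp_unique_kmers(one, k, canonical);
  }
  return out;
}

typedef std::unordered_map<uint64_t, double> ContribCache;

static double kmerContribution(uint64_t w, const std::vector<uint64_t>& f1,
                               const std::vector<uint64_t>& f2,
                               const NumericVector& wt, bool both, int km1,
                               uint64_t mask, int minMatch, ContribCache& cache) {
  ContribCache::const_iterator it = cache.find(w);
  if (it != cache.end()) return it->second;
  double acc = 0.0;
  for (size_t j = 0; j < f1.size(); ++j) {
    int s = scorePacked(w, f1[j], both ? f2[j] : 0, both, km1, mask, minMatch);
    if (s) acc += wt[j] * s;
  }
  cache[w] = acc;
  return acc;
}

// contribution of the k-mer starting at each position (0 for windows with
// non-ACGT bases); the linear-time scanning primitive
// [[Rcpp::export]]
NumericVector cpp_position_contribs(std::string seq, CharacterVector feats,
                                    NumericVector wt, int k, int minMatch,
                                    bool both) {
  int L = (int)seq.size(), km1 = k - 1;
  if (L < k) stop("sequence shorter than k");
  uint64_t mask = nibbleMask(km1);
  std::vector<uint64_t> f1, f2;
  packFeatures(feats, k, both, f1, f2);
  ContribCache cache;
  NumericVector out(L - k + 1);
  for (int i = 0; i + k <= L; ++i) {
    uint64_t p;
    if (packKmer(seq.c_str() + i, k, &p))
      out[i] = kmerContribution(p, f1, f2, wt, both, km1, mask, minMatch, cache);
  }
  return out;
}

// model score (bias + sum of k-mer contributions) per sequence, sharing the
// contribution hash across sequences
// [[Rcpp::export]]
NumericVector cpp_predict_seqs(CharacterVector seqs, CharacterVector feats,
                               NumericVector wt, double bias, int k,
                               int minMatch, bool both) {
  int ns = seqs.size(), km1 = k - 1;
  uint64_t mask = nibbleMask(km1);
  std::vector<uint64_t> f1, f2;
  packFeatures(feats, k, both, f1, f2);
  ContribCache cache;
  NumericVector out(ns);
  for (int i = 0; i < ns; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = (int)s.size();
    if (L < k) stop("sequence shorter than k");
    double acc = bias;
    for (int p = 0; p + k <= L; ++p) {
      uint64_t w;
      if (packKmer(s.c_str() + p, k, &w))
        acc += kmerContribution(w, f1, f2, wt, both, km1, mask, minMatch, cache);
    }
    out[i] = acc;
  }
  return out;
}

// contribution-table entries for explicitly supplied k-mers
// [[Rcpp::export]]
NumericVector cpp_kmer_contribs(CharacterVector kmers, CharacterVector feats,
                                NumericVector wt, int k, int minMatch,
                                bool both) {
  int n = kmers.size(), km1 = k - 1;
  uint64_t mask = nibbleMask(km1);
  std::vector<uint64_t> f1, f2;
  packFeatures(feats, k, both, f1, f2);
  ContribCache cache;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t p;
    if ((int)s.size() != k || !packKmer(s.c_str(), k, &p))
      stop("invalid k-mer '" + s + "'");
    out[i] = kmerContribution(p, f1, f2, wt, both, km1, mask, minMatch, cache);
  }
  return out;
}

static inline int matchCount(const std::string& kmer, const std::string& seq,
                             int off) {
  int c = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    char a = kmer[i], b = seq[off + i];
    if (a == b && baseCode(a) >= 0) ++c;
  }
  return c;
}

// best ungapped alignment score of each k-mer against each sequence
// [[Rcpp::export]]
IntegerMatrix cpp_alignment_scores(CharacterVector kmers, CharacterVector seqs,
                                   bool both) {
  int nk = kmers.size(), ns = seqs.size();
  IntegerMatrix out(nk, ns);
  std::vector<std::string> ss(ns);
  for (int j = 0; j < ns; ++j) ss[j] = as<std::string>(seqs[j]);
  for (int i = 0; i < nk; ++i) {
    std::string km = as<std::string>(kmers[i]);
    std::string kmrc = revComp(km);
    int k = (int)km.size();
    for (int j = 0; j < ns; ++j) {
      const std::string& s = ss[j];
      int L = (int)s.size();
      if (L < k) stop("sequence shorter than the k-mer");
      int best = 0;
      for (int off = 0; off + k <= L; ++off) {
        int c = matchCount(km, s, off);
        if (c > best) best = c;
        if (both) {
          c = matchCount(kmrc, s, off);
          if (c > best) best = c;
        }
      }
      out(i, j) = best;
    }
  }
  return out;
}

// best alignment of one k-mer to each sequence: score, 0-based offset and
// strand (0 = forward, 1 = the window's reverse complement matches the k-mer).
// Ties resolved toward the forward strand, then the smaller offset.
// [[Rcpp::export]]
IntegerMatrix cpp_align_best(std::string kmer, CharacterVector seqs, bool both) {
  int ns = seqs.size(), k = (int)kmer.size();
  std::string kmrc = revComp(kmer);
  IntegerMatrix out(ns, 3);
  for (int j = 0; j < ns; ++j) {
    std::string s = as<std::string>(seqs[j]);
    int L = (int)s.size();
    if (L < k) stop("sequence shorter than the k-mer");
    int best = -1, boff = 0, bstr = 0;
    for (int off = 0; off + k <= L; ++off) {
      int c = matchCount(kmer, s, off);
      if (c > best) { best = c; boff = off; bstr = 0; }
    }
    if (both) {
      for (int off = 0; off + k <= L; ++off) {
        int c = matchCount(kmrc, s, off);
        if (c > best) { best = c; boff = off; bstr = 1; }
      }
    }
    out(j, 0) = best;
    out(j, 1) = boff;
    out(j, 2) = bstr;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    out[i] = revComp(as<std::string>(seqs[i]));
  return out;
}
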