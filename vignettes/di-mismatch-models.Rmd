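---
title: "Modeling TF binding with the di-mismatch kernel: methods and design notes"
author: "dimismatch maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling TF binding with the di-mismatch kernel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimismatch)
```

## The problem

A transcription factor (TF) binds double-stranded DNA with sequence
preferences that a position-specific scoring matrix (PSSM) often captures
only coarsely. Protein binding microarrays (PBMs) measure a TF's
fluorescence intensity over tens of thousands of designed 36-nt probes,
and ChIP-seq locates its occupied sites in vivo. This package learns
binding models *discriminatively* from both data types: support vector
regression (SVR) maps probe sequence to binding intensity, and a support
vector machine (SVM) separates 60-bp ChIP peak windows from flanking
background. Both operate in the explicit feature space of a **di-mismatch
string kernel**, and the trained weight vectors double as linear scanners
of genomic sequence.

## The di-mismatch kernel

A k-mer is viewed through its $k-1$ overlapping dinucleotides. The
di-mismatch score of two k-mers $u, f$ counts the dinucleotide positions
at which they agree, and is set to zero when the count falls below the
threshold $k - 1 - m$, where $m$ is the maximum tolerated number of
mismatching dinucleotides. A single substituted base disrupts up to two
dinucleotides, but adjacent substitutions share dinucleotides, so the
score inherently favors *consecutive* over scattered mismatches: in a
13-mer pair, four consecutive interior substitutions cost 5 of the 12
dinucleotides, while four isolated substitutions at positions 1, 5, 9 and
13 cost 6.

```{r kernel}
raw <- diMismatchParams(13, 12, "single")   # threshold 0: raw counts
a <- "ACGTACGTACGTA"
b <- a; substr(b, 5, 8) <- "TTGC"           # 4 consecutive mismatches
12 - diMismatchScore(a, b, raw)
```

A sequence $x$ maps to the feature vector whose entry for dictionary
k-mer $f$ is $\sum_{s \in \text{windows}(x)} d(s, f)$ — a **sum** over all
length-$k$ windows, not a maximum; summation makes the feature map linear
in window contributions, which is what permits the fast scanning path
below. For double-stranded DNA (`strandMode = "both"`, the default) the
dictionary is strand-canonicalized and each window scores the better of a
feature and its reverse complement, which makes every downstream score
invariant under reverse complementation of the input. Windows containing
non-ACGT characters contribute nothing.

The standard model parameters are $(k, m) = (13, 5)$: at least 7 of 12
matching dinucleotides, i.e. at least 8 matching characters, mirroring the
8-mer coverage guarantee of PBM probe designs. Parameter pairs are
constrained to $k - m \ge 8$ wherever models are trained. The
implementation packs the dinucleotide codes of a k-mer into one 64-bit
word (4 bits each), which limits $k$ to 16 — comfortably above every
setting used in practice — and reduces a score evaluation to an XOR plus
a nibble population count.

## From probes to a regression model

The PBM pipeline is:

1. **Normalization** (`normalizeIntensities`): robust z-scores of
   log-intensities, $(\log y - \text{median}) / \text{MAD}$. The exact
   transform matters little downstream (every consumer is
   rank-based or tolerant to monotone rescaling); robustness matters
   because a PBM has a heavy right tail of bound probes.
2. **Tail sampling** (`sampleTrainingProbes`): positives are probes with
   normalized intensity at or above `zThreshold` (default 4.0), with a
   fallback to the top 500 when fewer qualify; the same number of
   negatives comes from the bottom of the distribution. Training on the
   tails concentrates the regression on the dynamic range that carries
   sequence signal instead of the unbound bulk.
3. **Feature selection** (`selectFeatures`): every k-mer occurring in the
   sampled probes is a candidate; features are ranked by the absolute
   difference between their mean feature value over positives and over
   negatives, and at most `maxFeatures` (default 4000) are kept. Ties
   break lexicographically so runs are reproducible.
4. **SVR** (`trainRegressor`): epsilon-insensitive regression with a
   linear kernel on the explicit features, $\epsilon = 0.1$ in all
   standard runs. The primal weight vector and bias are extracted from
   the libsvm solution (e1071), so a model is just one weight per k-mer.

The regularization constant $C$ is not pinned by the training protocol;
the config default is 1.0. Because the di-mismatch feature map gives every
training probe a partly private set of features, a weakly regularized SVR
can memorize training intensities and generalize poorly across array
designs. `trainRegressor(costGrid = )` therefore offers nested model
selection: $C$ is chosen from a grid by k-fold cross-validation *within
the training sample* (held-out Spearman correlation), never touching test
data. `crossDesignEvaluate` enables this by default with the grid
$10^{-4} \ldots 10^{0}$; on synthetic designs the selection lands at the
strongly regularized end and roughly doubles held-out detection.

Model quality is reported as the **detection of the top 100 probes**: the
overlap between the 100 highest-predicted and 100 highest-measured probes
of a held-out array design, averaged over the two train/test directions.

## The in vivo classifier and genome scanning

`extractTrainingWindows` turns the top 1000 peaks into 60-bp positive
windows centered on summits and 60-bp negatives whose centers sit 300 bp
to the left, skipping windows that would leave the chromosome or are more
than half ambiguous. `trainClassifier` fits a soft-margin linear SVM with
the standard $(13, 5)$ kernel; `crossvalAUC` reports stratified 10-fold
cross-validated ROC AUCs.

Two design choices in `crossvalAUC` deserve note. First, feature
*selection* runs inside every training fold — selection on the full data
would leak labels and inflate the permutation null well above 0.5. The
candidate *dictionary* (the set of occurring k-mers), by contrast, is
built once from the sequences alone; it is label-free. Second, the
per-fold class means needed for selection are recovered from a single
grouped pairwise pass (training-fold sum = class total minus held-out
fold sum), which makes 10-fold selection cost one pass instead of ten
with bit-identical results.

Scanning (`scanSequence`, `maxWindowScore`, `rankRegions`) exploits the
linearity of the model: the contribution of every distinct window k-mer,
$\sum_f w_f\, d(u, f)$, is computed once and cached, so scoring a region
is one table lookup per position plus a rolling window sum. The fast path
is tested to $10^{-9}$ against a brute-force oracle. Windows of ambiguous
sequence score exactly the bias. Regions are ranked by the height of
their best window, the criterion used for intergenic-region occupancy
prediction; 60-mers are scored by the maximum over their 25 36-nt
windows when a PBM-derived (regression) model is applied in vivo.

## Baselines

`computeEscores` implements 8-mer enrichment scores as the rescaled
Mann–Whitney statistic AUC $-$ 0.5 over the full probe ranking, in
$[-0.5, 0.5]$. The published PBM statistic is a split-half variant tied
to the array's replicate structure, which a plain probe table does not
carry; the full-ranking form preserves its meaning (how exclusively an
8-mer occupies the bound end of the ranking) and its scale. Patterns are
contiguous and strand-merged; `minSupport` (default 20, calibrated for
~40K-probe designs — scale it with the design, e.g. 5 at 4000 probes)
drops ultra-rare patterns whose rank statistic would be noise. `emaxScore`
scores a sequence by its best contained 8-mer, optionally ignoring 8-mers
below the conventional 0.35 threshold and returning the $-0.5$ sentinel
when nothing scores. `zmaxScore` replaces E-scores with median training
intensities. `pssmLogOddsMax` scans a PSSM in log-odds form (pseudocount
folded in so a uniform matrix scores identically zero) over both strands.

## Feature analysis

To see what a trained model has learned, each k-mer feature is embedded
as the vector of its best ungapped alignment scores (matching positions,
both strands) against the positive training sequences
(`alignmentScoreVectors`); k-mers supported by the same probes or peaks
land near each other regardless of exact sequence. `clusterModelFeatures`
runs seeded k-means with $k = 2$ (10 restarts, Euclidean distance on the
raw vectors) — two clusters, because the phenomenon of interest is a
primary motif standing apart from a secondary or cofactor motif — keeps
the top 500 k-mers per cluster by model weight, and projects the kept set
to two dimensions by PCA. A cluster's representative is the member in the
top weight quartile nearest the centroid; `expandFeatureToPSSM` turns it
into a motif by stacking the best-aligned windows of the top 50 positive
sequences (strand-resolved) into a frequency matrix.
`retrainOnFeatureSubset` refits a model on one cluster's k-mers, which
quantifies each motif's contribution to in vivo prediction: on synthetic
data where only one motif drives the labels, the matching cluster's model
beats the other by a wide AUC margin, reproducing the primary/secondary
dissection this analysis is designed for. Model weights enter the
clustering only through the post-hoc filtering and representative choice,
never the distance.

## The synthetic testbed

`simulatePBMExperiment` and `simulateChipExperiment` generate the data
every recovery test runs on. The generative model is deliberately simple
but biophysically shaped:

* Probes are uniform random 36-mers (real designs are de Bruijn
  constructions guaranteeing 10-mer coverage; coverage is irrelevant for
  exercising the pipeline, and this divergence is intentional).
* A planted site, sampled base-by-base from a sharp PSSM (0.85 consensus
  probability, octamer ATGCAAAT by default), lands in a 5% fraction of
  probes at a random offset and strand.
* Log-intensity is the sum over windows of
  $\mathrm{softplus}(\text{log-odds} - \mu)$ times an effect size
  (default 2), plus Gaussian noise (SD 0.5). The chemical-potential
  offset $\mu = 5$ sits between the log-odds of a 6/8 and a 7/8 consensus
  match, so windows below a near-perfect site contribute essentially
  nothing and — as in real PBM experiments — only a few hundred probes
  per design show binding. Without the offset, diffuse sub-site partial
  matches accumulate into a large unpredictable background component that
  no k-mer model (nor the generative PSSM itself) can rank.
* The two array designs are disjoint by construction (collisions are
  regenerated), giving an honest cross-design test.
* The ChIP generator spaces summits at least 600 bp apart, plants a
  *bound* site in each positive window — sites are rejection-sampled with
  acceptance probability $\sigma(\text{log-odds} - \mu)$, the
  affinity-weighted distribution appropriate under observed binding
  events — and optionally plants a cofactor site beside or instead of the
  primary in a configurable fraction of positives. Windows, peaks and
  genome are derived through the same `extractTrainingWindows` code path
  users run.

What passing tests on this generator do show: the whole pipeline —
normalization, tail sampling, selection, training, scanning, baselines,
clustering — recovers planted structure from realistic-sized inputs with
correct strand handling and reproducible seeding. What they do not show:
performance on real PBM noise (spatial artifacts, replicate structure,
saturation), real genomic sequence composition, or real chromatin
effects; conclusions about biological data require biological data.

## Numerical choices and degenerate inputs

* All tie-breaks (feature ranking, detection top lists, representatives,
  region ranking) resolve by lexicographic id, making every result
  order-invariant and reproducible.
* Feature order is lexicographic; floating accumulation follows fixed
  iteration order; every stochastic step takes an explicit seed.
* Constant labels yield a constant model with a warning; single-class
  window sets, empty feature spaces, too-short sequences and
  unsatisfiable peak spacing raise errors naming the problem.
* `normalizeIntensities` floors a zero MAD with the scaled IQR and then
  1, so constant intensities normalize to zeros rather than NaN;
  non-positive intensities are shifted with a warning before logs.
* The MEME reader renormalizes rows off by more than $10^{-6}$ with a
  warning; the writer emits 8 decimals so round-trips are silent.
* The representation-equivalence guarantee is tested as: the package's
  explicit weight-vector predictions equal the fitted solver's own
  `predict` on identical data to $10^{-6}$, and the hash-table scanning
  path equals the materialized feature map to $10^{-9}$.

## Problem sizes used by the automated checks

The test suite exercises the synthetic pipeline at 4000 probes per design
with at most 1000 selected features (cross-design recovery, 10 seeds),
1000 peaks / 2000 windows for the in vivo cross-validation and its
permutation control, and 300 peaks for the cluster-retraining contrast —
sizes chosen so the full suite completes on a single CPU in well under
half an hour while keeping every recovery effect far from its decision
threshold.

## Known limitations

* The E-score implementation is the full-ranking Mann–Whitney form, not
  the published split-half statistic; absolute values can differ slightly
  near the extremes even though the ordering is preserved.
* Gapped 8-mer patterns, array spatial correction, replicate merging and
  peak calling are out of scope; peaks are inputs.
* The packed-word kernel limits $k \le 16$.
* `retrainOnFeatureSubset` inherits its regularization from the caller;
  when comparing cluster-restricted models, hold $C$ fixed across the
  clusters being compared (e.g. the parent model's CV-selected value), as
  re-tuning on a restricted space would confound the comparison.
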