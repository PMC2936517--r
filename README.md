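# dimismatch

Discriminative models of transcription-factor (TF) DNA binding, learned
from high-resolution in vitro and in vivo data.

Protein binding microarrays (PBMs) measure a TF's binding intensity over
~40K designed 36-nt probes; ChIP-seq locates its occupied sites in vivo.
PSSMs underfit such data, and rank-based 8-mer profiles (E-scores) are
informative but unwieldy. This package instead *trains* binding models:
support vector regression (SVR) from probe sequence to intensity, and a
support vector machine (SVM) separating 60-bp ChIP peak windows from
flanking background, both in the explicit feature space of a
**di-mismatch string kernel**.

## The kernel

The di-mismatch score of two k-mers counts their matching overlapping
dinucleotides (of the k − 1 total) and is zeroed when the count falls
below k − 1 − m, with m the maximum tolerated number of mismatching
dinucleotides. Because adjacent substitutions share dinucleotides, the
kernel favors consecutive over scattered mismatches: in a 13-mer pair,
four consecutive interior substitutions cost 5 of 12 dinucleotides, four
isolated ones (positions 1, 5, 9, 13) cost 6. A sequence x maps to
Φ(x)<sub>f</sub> = Σ<sub>windows s of x</sub> d(s, f) over a dictionary
of training k-mers; the standard model choice (k, m) = (13, 5) requires
at least 8 matching characters. Trained weight vectors w yield the score
w·Φ(x) + b, computed in linear time through a precomputed per-k-mer
contribution table, so models scan genomic regions directly.

Alongside the models the package provides the field's baseline scorers
(8-mer E-scores with E-max, Z-max, PSSM log-odds scanning), a
feature-analysis procedure that clusters model k-mers to expose primary,
secondary and cofactor motifs, and seeded synthetic PBM/ChIP generators
with planted motifs for end-to-end validation.

## Worked example

Simulate a pair of disjoint PBM array designs with a planted ATGCAAAT
motif, run the full cross-design protocol (normalize → sample intensity
tails → select ≤1000 k-mer features → SVR with nested cost selection →
score the held-out design), then scan a region:

```r
library(dimismatch)

spec <- syntheticSpec(seed = 42, nProbes = 2000)
designs <- simulatePBMExperiment(spec)
res <- crossDesignEvaluate(designs$designA, designs$designB,
                           trainingConfig(maxFeatures = 1000))
res$detection
#> AtoB BtoA
#>   80   78
res$average
#> [1] 79
```

Of the 100 brightest probes of each held-out design, the SVR trained on
the other design recovers 80 and 78 (chance at this scale is
100²/2000 = 5). The model is an explicit weight per 13-mer:

```r
model <- res$models$AtoB
model
#> LinearSequenceModel (regression): 1000 features, bias -0.7481
#>   provenance: SVR on 1000 probes from 'designA', 1000 features, CV-selected C = 1e-04
round(head(sort(modelWeights(model), decreasing = TRUE), 3), 4)
#> TATTTGCATATAA ATTTGCATAAATG CATTTGCATAGGG
#>        0.0162        0.0157        0.0155
```

The top-weighted 13-mers share the ATTTGCAT core — the strand-canonical
form of the planted ATGCAAAT. Scanning locates a planted site (here
ATGCAAAT written at positions 201-208 of a random 500-nt region):

```r
set.seed(99)
region <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
substr(region, 201, 208) <- "ATGCAAAT"
prof <- scanSequence(model, region, windowLength = 36)
length(windowScores(prof)); which.max(windowScores(prof))
#> [1] 465
#> [1] 181        # windows 181..216 overlap the site at 201-208
```

`extractTrainingWindows` + `runChipTraining` build and cross-validate the
in vivo SVM from a peak list and genome FASTA; `computeEscores`,
`emaxScore`, `zmaxScore` and `pssmLogOddsMax` provide the baselines;
`alignmentScoreVectors` → `clusterModelFeatures` →
`expandFeatureToPSSM` / `retrainOnFeatureSubset` dissect a trained model
into its motif clusters. A thin CLI over these functions is at
`inst/scripts/dimismatch-cli.R`. The methods vignette
(`vignettes/di-mismatch-models.Rmd`) documents the model, parameter
choices and the synthetic generator's assumptions.

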